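"""Serial-coalescent simulator backend.

Reads a JSON job description, simulates serially sampled haploid
genomes under a piecewise-constant single-population demography with
recombination and infinite-sites-like binary mutation, and writes
plain-text matrices plus a genealogical truth table.

Invoked by the R front end; not a user-facing entry point.

Job JSON fields:
  out_dir          directory for output TSVs (must exist)
  chrom_lengths    list of chromosome lengths in bp
  recomb_rate      per-bp per-generation recombination rate
  mut_rate         per-bp per-generation mutation rate
  sample_times     generations before present, ascending
  haploids_per_time  haploid lineages sampled at each time
  epochs           list of {start_time, ne}; first start_time == 0
  seeds            one RNG seed per chromosome (ints in [1, 2^31))

Outputs (all tab-separated, written to out_dir):
  sites.tsv   chrom, pos (1-based), ancestral, derived
  calls.tsv   one row per site, one 0/1 column per haploid
  haploids.tsv  haploid, time
  truth.tsv   haploid, chrom, span_bp, mean_root_path (generations,
              tree-span-weighted mean of time(root) - time(sample))
"""

import json
import sys

import msprime
import numpy as np


def build_demography(epochs):
    demog = msprime.Demography()
    demog.add_population(name="pop", initial_size=epochs[0]["ne"])
    for ep in epochs[1:]:
        demog.add_population_parameters_change(
            time=ep["start_time"], initial_size=ep["ne"], population="pop"
        )
    return demog


def simulate_chromosome(cfg, chrom_index, seed):
    length = cfg["chrom_lengths"][chrom_index]
    demog = build_demography(cfg["epochs"])
    samples = [
        msprime.SampleSet(cfg["haploids_per_time"], time=t, ploidy=1)
        for t in cfg["sample_times"]
    ]
    ts = msprime.sim_ancestry(
        samples=samples,
        demography=demog,
        sequence_length=length,
        recombination_rate=cfg["recomb_rate"],
        random_seed=seed,
    )
    # Binary 0/1 mutations on a discrete genome; sites hit more than once
    # are dropped afterwards so every retained site is a clean
    # single-origin ancestral/derived pair (infinite-sites behaviour).
    mts = msprime.sim_mutations(
        ts,
        rate=cfg["mut_rate"],
        random_seed=seed + 1,
        model=msprime.BinaryMutationModel(),
        discrete_genome=True,
    )
    keep = np.array(
        [len(site.mutations) == 1 for site in mts.sites()], dtype=bool
    )
    geno = mts.genotype_matrix()[keep, :]
    pos = mts.tables.sites.position[keep].astype(np.int64) + 1  # 1-based

    # Tree-span-weighted mean root-to-sample path length per haploid.
    sample_nodes = mts.samples()
    node_time = mts.tables.nodes.time
    total_span = 0.0
    acc = np.zeros(len(sample_nodes))
    for tree in mts.trees():
        span = tree.interval.right - tree.interval.left
        root_time = max(node_time[r] for r in tree.roots)
        acc += span * (root_time - node_time[sample_nodes])
        total_span += span
    mean_path = acc / total_span
    return pos, geno, mean_path, length


def main(job_path):
    with open(job_path) as fh:
        cfg = json.load(fh)
    # R's JSON writer unboxes length-1 vectors to scalars
    for key in ("chrom_lengths", "sample_times", "seeds"):
        if not isinstance(cfg[key], list):
            cfg[key] = [cfg[key]]
    if isinstance(cfg["epochs"], dict):
        cfg["epochs"] = [cfg["epochs"]]
    out = cfg["out_dir"].rstrip("/")
    times = np.repeat(cfg["sample_times"], cfg["haploids_per_time"])
    hap_ids = [
        "hap_t%d_%02d" % (t, i + 1)
        for t in cfg["sample_times"]
        for i in range(cfg["haploids_per_time"])
    ]

    all_sites = []
    all_geno = []
    truth_rows = []
    for ci, seed in enumerate(cfg["seeds"]):
        chrom = "chr%d" % (ci + 1)
        pos, geno, mean_path, length = simulate_chromosome(cfg, ci, int(seed))
        all_sites.append(
            np.column_stack([np.repeat(chrom, len(pos)), pos.astype(str)])
        )
        all_geno.append(geno)
        for hap, mp in zip(hap_ids, mean_path):
            truth_rows.append((hap, chrom, length, mp))

    sites = np.concatenate(all_sites)
    geno = np.concatenate(all_geno)

    with open(out + "/sites.tsv", "w") as fh:
        fh.write("chrom\tpos\tancestral\tderived\n")
        for chrom, p in sites:
            fh.write("%s\t%s\tA\tT\n" % (chrom, p))
    header = "\t".join(hap_ids)
    np.savetxt(
        out + "/calls.tsv", geno, fmt="%d", delimiter="\t",
        header=header, comments="",
    )
    with open(out + "/haploids.tsv", "w") as fh:
        fh.write("haploid\ttime\n")
        for hap, t in zip(hap_ids, times):
            fh.write("%s\t%d\n" % (hap, t))
    with open(out + "/truth.tsv", "w") as fh:
        fh.write("haploid\tchrom\tspan_bp\tmean_root_path\n")
        for hap, chrom, length, mp in truth_rows:
            fh.write("%s\t%s\t%d\t%.6f\n" % (hap, chrom, length, mp))


if __name__ == "__main__":
    main(sys.argv[1])
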