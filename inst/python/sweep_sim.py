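"""Coalescent simulation backend.

Reads a replicate manifest (TSV) and a piecewise-constant demography (TSV)
and writes, for every replicate, the unphased diploid dosage matrix of the
simulated region.  Neutral replicates use the standard coalescent with
recombination; sweep replicates use msprime's structured-coalescent sweep
model (SweepGenicSelection), run to fixation `tau` (units of 4*N0
generations, N0 = most recent epoch size) before sampling.  Hard sweeps
start from a single copy (frequency 1/2N0); soft sweeps start from the
standing frequency f0, below which the lineages coalesce neutrally.

Output text format, one block per replicate:
    >ID NSITES
    pos_1 pos_2 ... pos_S          (0-based integer positions)
    <n lines of S dosage digits (0/1/2), one line per individual>
Failed replicates emit a line "!ID message" and a nonzero exit status.
"""

import argparse
import sys

import msprime
import numpy as np


def read_tsv(path):
    with open(path) as fh:
        header = fh.readline().rstrip("\n").split("\t")
        rows = [dict(zip(header, line.rstrip("\n").split("\t")))
                for line in fh if line.strip()]
    return rows


def build_demography(epochs):
    dem = msprime.Demography()
    dem.add_population(initial_size=float(epochs[0]["Ne"]))
    for ep in epochs[1:]:
        dem.add_population_parameters_change(
            time=float(ep["time_generations"]),
            initial_size=float(ep["Ne"]))
    return dem


def simulate(row, dem, n0):
    L = float(row["L"])
    n = int(row["n"])
    seed = int(row["seed"])
    s = float(row["s"])
    models = None
    if s > 0:
        tau_gens = float(row["tau"]) * 4.0 * n0
        f0 = float(row["f0"])
        start = max(f0, 1.0 / (2 * n0))
        end = 1.0 - 1.0 / (2 * n0)
        sweep = msprime.SweepGenicSelection(
            position=min(max(float(row["sweep_pos"]), 1.0), L - 1.0),
            start_frequency=start, end_frequency=end, s=s, dt=1e-6)
        models = []
        if tau_gens > 0:
            models.append(msprime.StandardCoalescent(duration=tau_gens))
        models.append(sweep)
        models.append(msprime.StandardCoalescent())
    ts = msprime.sim_ancestry(
        samples=n, ploidy=2, sequence_length=L,
        recombination_rate=float(row["r"]), demography=dem,
        model=models, random_seed=seed)
    mts = msprime.sim_mutations(
        ts, rate=float(row["mu"]), random_seed=seed,
        model=msprime.BinaryMutationModel(), discrete_genome=True)
    G = mts.genotype_matrix()            # sites x haploid samples, 0/1
    pos = np.array([int(site.position) for site in mts.sites()])
    # drop sites monomorphic after recurrent/back mutation
    ac = G.sum(axis=1)
    keep = (ac > 0) & (ac < G.shape[1])
    G = G[keep]
    pos = pos[keep]
    D = (G[:, 0::2] + G[:, 1::2]).T      # individuals x sites
    return pos, D


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--manifest", required=True)
    ap.add_argument("--demography", required=True)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()

    rows = read_tsv(args.manifest)
    epochs = read_tsv(args.demography)
    dem = build_demography(epochs)
    n0 = float(epochs[0]["Ne"])

    failed = False
    with open(args.out, "w") as out:
        for row in rows:
            try:
                pos, D = simulate(row, dem, n0)
            except Exception as exc:  # report and continue
                out.write("!%s %s\n" % (row["id"], str(exc).replace("\n", " ")))
                failed = True
                continue
            out.write(">%s %d\n" % (row["id"], len(pos)))
            out.write(" ".join(str(p) for p in pos) + "\n")
            digits = np.char.mod("%d", D)
            for i in range(D.shape[0]):
                out.write("".join(digits[i]) + "\n")
    sys.exit(1 if failed else 0)


if __name__ == "__main__":
    main()
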