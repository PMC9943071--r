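"""Independent coalescent oracle for archaic allele-sharing proportions.

Simulates the same demography as the package's engine with msprime, places
one branch-length-weighted mutation per genealogy, and prints the sharing
proportion (YRI mac>1 variants with a derived allele in >=1 archaic haploid)
plus its binomial standard error.  Used only as a cross-check in tests.

Usage:
  python sharing_oracle.py single  N_LOCI SEED NE N_YRI
  python sharing_oracle.py full    N_LOCI SEED
"""
import sys

import msprime
import numpy as np

GEN = 29.0


def full_demography():
    d = msprime.Demography()
    d.add_population(name="YRI", initial_size=14474)
    d.add_population(name="vindija", initial_size=1000)
    d.add_population(name="chagyrskaya", initial_size=1000)
    d.add_population(name="altai", initial_size=1000)
    d.add_population(name="denisovan", initial_size=1000)
    d.add_population(name="NEA", initial_size=1000)
    d.add_population(name="ARC", initial_size=1000)
    d.add_population(name="ARCD", initial_size=1000)
    d.add_population(name="ROOT", initial_size=14474)
    d.add_population_split(time=90000 / GEN, derived=["vindija", "chagyrskaya"],
                           ancestral="NEA")
    d.add_population_split(time=130000 / GEN, derived=["NEA", "altai"],
                           ancestral="ARC")
    d.add_population_split(time=400000 / GEN, derived=["ARC", "denisovan"],
                           ancestral="ARCD")
    d.add_population_split(time=700000 / GEN, derived=["YRI", "ARCD"],
                           ancestral="ROOT")
    return d


def sharing(reps, n_yri, n_arch_hap, rng):
    num = den = 0
    for ts in reps:
        tree = ts.first()
        lengths = np.array([tree.branch_length(u) for u in range(ts.num_nodes)])
        total = lengths.sum()
        pick = rng.uniform(0, total)
        acc = 0.0
        edge = None
        for u in range(ts.num_nodes):
            if lengths[u] == 0:
                continue
            if pick < acc + lengths[u]:
                edge = u
                break
            acc += lengths[u]
        derived = set(tree.leaves(edge))
        d_yri = sum(1 for v in derived if v < n_yri)
        if d_yri >= 2 and (n_yri - d_yri) >= 2:
            den += 1
            if any(v >= n_yri for v in derived):
                num += 1
    return num, den


def main():
    mode = sys.argv[1]
    n_loci = int(sys.argv[2])
    seed = int(sys.argv[3])
    rng = np.random.default_rng(seed)
    if mode == "single":
        ne = float(sys.argv[4])
        n_yri = int(sys.argv[5])
        reps = msprime.sim_ancestry(
            samples=n_yri + 8, ploidy=1, population_size=ne,
            num_replicates=n_loci, random_seed=seed)
        num, den = sharing(reps, n_yri, 8, rng)
    else:
        d = full_demography()
        samples = [
            msprime.SampleSet(216, population="YRI", ploidy=1),
            msprime.SampleSet(2, population="vindija", ploidy=1),
            msprime.SampleSet(2, population="chagyrskaya", ploidy=1),
            msprime.SampleSet(2, population="altai", ploidy=1),
            msprime.SampleSet(2, population="denisovan", ploidy=1),
        ]
        reps = msprime.sim_ancestry(samples=samples, demography=d,
                                    num_replicates=n_loci, random_seed=seed)
        num, den = sharing(reps, 216, 8, rng)
    p = num / den if den else float("nan")
    se = (p * (1 - p) / den) ** 0.5 if den else float("nan")
    print(f"{p:.6f} {se:.6f} {den}")


if __name__ == "__main__":
    main()
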