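# molautofix

Molecule auto-correction for R: identify what is chemically wrong with a
molecular graph and repair it by tree search, staying as close as
possible to the input structure.

Virtual molecule generators (genetic algorithms, recurrent networks,
latent-space optimizers) routinely propose molecules with impossible
valences, absurd charge states or bonding patterns absent from real
chemistry. `molautofix` works like a spell checker for such graphs:

* **Featurization.** Every atom becomes an integer *atom key*
  `(D, V, Z, Q, H)` — degree, valence (sum of bond orders), atomic
  number, formal charge, hydrogen count — ordered by decreasing
  significance, together with its prefix *partial keys*. Bonds become
  *(AK1, AK2, B)* bond keys and every atom additionally contributes a
  Morgan-hashed *circular environment key* of radius *r* (ECFP-style).
* **Chemical dictionary.** Key frequencies counted over a reference
  library of drug-like molecules. A key with count `> t` (default
  `t = 0`) is *familiar*; anything else is *foreign*. Familiarity of a
  molecule with `n` keys, `n_f` of them familiar:
  `f1 = n_f / n` and `f2 = 1 / (n − n_f + 1)`, both equal to 1 exactly
  for a correct molecule.
* **Correction search.** The molecule is the root of a tree whose edges
  are single graph edits (hydrogen/charge/element/bond-order changes,
  deletions, insertions). An *expansion policy* diagnoses the most
  significant foreign key — e.g. a hexavalent carbon's `(4,6,6)` key is
  foreign while `(4,6)` is familiar, blaming the atomic number — and
  proposes repairs ordered by how often each replacement value occurs in
  the reference. A *selection policy* (`bfs`, `greedy_f2`,
  `greedy_ratio`, `uct`, `astar`, `mlr`, `objective`) chooses which
  vertex to expand next; the search stops at the first fully familiar
  molecule.

Chemically invalid molecules are first-class inputs throughout: the
SMILES/SDF readers perform no valence rejection.

## Worked example

```r
library(molautofix)

# a dictionary from the bundled drug-like reference list (238 molecules)
ref  <- druglike_reference()
dict <- chemical_dictionary(lapply(ref, parse_smiles), radius = 1)

# a chemically impossible input: hypervalent sulfur in fused strained rings
bad <- parse_smiles("OOC1[C]2#S1C2")
familiarity_report(bad, dict)
#> <familiarity_report> n=19 (atoms 6, bonds 7, environments 6)
#>   familiar 5/19: f1 = 0.2632, f2 = 0.0667

res <- correct_molecule(bad, dict, policy = "greedy_f2")
res
#> <correction_result> solved (policy greedy_f2)
#>   output: OC1C2C1C2
#>   f1 = 1.0000, f2 = 1.0000, d_root = 0.8846
#>   tree size 42, 41 iterations, solution depth 3
```

The report says only 5 of the input's 19 structural keys occur in the
reference chemistry (`f1 = 0.26`). Three edits later every key is
familiar (`f1 = 1`): the impossible sulfur bridge is gone and the output
is an ordinary bicyclic alcohol. `d_root` is the ECFP4 Tanimoto distance
between input and output — lower means more of the input was preserved,
and explorative policies (`bfs`, `astar`, `mlr`, `uct`) trade more
search effort for closer outputs.

The expansion policy's frequency ranking in one picture: given two
sulfones and one selenone as reference, a hexavalent carbon is repaired
by trying sulfur before selenium:

```r
d <- chemical_dictionary(c("CS(C)(=O)=O", "CS(C)(=O)=O", "C[Se](C)(=O)=O"))
successor_values(d, c(4, 6), "Z")
#>   value count
#> 1    16     2
#> 2    34     1
```

A command-line interface ships in `exec/`:

```sh
molautofix build-dict ref.smi -r 1 -o dict.tsv
molautofix break in.smi -n 10 --seed 7 -o broken.smi
molautofix correct broken.smi -d dict.tsv --policy mlr -o out.tsv
molautofix benchmark -c config.yaml -o results.tsv
```

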