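# Shared fixtures: the bundled reference list and its radius-1 dictionary,
# built once per test run.

ref_smiles <- druglike_reference()
ref_mols <- lapply(ref_smiles, parse_smiles)
ref_dict <- chemical_dictionary(ref_mols, radius = 1)

# apply a random atom-index permutation to a molecule
permute_molgraph <- function(m, perm) {
  b <- m$bonds
  b[, 1L] <- match(b[, 1L], perm)
  b[, 2L] <- match(b[, 2L], perm)
  molgraph(Z = m$Z[perm], Q = m$Q[perm], H = m$H[perm], bonds = b)
}

# multiset of all key strings of a molecule (sorted, for isomorphism checks)
all_key_strings <- function(m, radius = 1) {
  ks <- featurize_molecule(m, radius)
  sort(c(ks$atom_keys, ks$bond_keys, ks$environment_keys))
}
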