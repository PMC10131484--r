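# shared fixtures, built once per test run; a 60-residue protein screened at
# moderate depth keeps the suite fast while exercising every pipeline stage
.fix <- new.env(parent = emptyenv())

fix_truth <- function() {
  if (is.null(.fix$truth))
    .fix$truth <- generate_truth(protein_length = 60,
                                 mutable_range = c(2, 60), seed = 5)
  .fix$truth
}

fix_counts <- function() {
  if (is.null(.fix$counts))
    .fix$counts <- simulate_screen(fix_truth(),
                                   screen_config(depth_per_tile = 5e5,
                                                 n_clones = 5e4, seed = 7))
  .fix$counts
}

fix_map <- function() {
  if (is.null(.fix$map))
    .fix$map <- activity_map(fix_counts(), n_boot = 0)
  .fix$map
}

# minimal single-chain PDB text for structure-annotation tests
write_toy_pdb <- function(path, residues = 1:5) {
  lines <- character(0)
  serial <- 0L
  for (r in residues) for (atom in c("N", "CA", "C", "O")) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
      serial, atom, r, r * 1.0, 0, 0, 1.00, 0.00,
      substr(atom, 1, 1)))
  }
  writeLines(c(lines, "END"), path)
  path
}
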