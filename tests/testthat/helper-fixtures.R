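# Shared fixtures, all built in code.

ethane_mol2 <- function() c(
  "@<TRIPOS>MOLECULE", "ethane", " 8 7 1", "SMALL", "USER_CHARGES",
  "@<TRIPOS>ATOM",
  "1 C1 0.000 0.000 0.000 C.3 1 LIG -0.060",
  "2 C2 1.540 0.000 0.000 C.3 1 LIG -0.060",
  "3 H1 -0.360 1.020 0.000 H 1 LIG 0.020",
  "4 H2 -0.360 -0.510 0.880 H 1 LIG 0.020",
  "5 H3 -0.360 -0.510 -0.880 H 1 LIG 0.020",
  "6 H4 1.900 1.020 0.000 H 1 LIG 0.020",
  "7 H5 1.900 -0.510 0.880 H 1 LIG 0.020",
  "8 H6 1.900 -0.510 -0.880 H 1 LIG 0.020",
  "@<TRIPOS>BOND",
  "1 1 2 1", "2 1 3 1", "3 1 4 1", "4 1 5 1", "5 1 6 1", "6 1 7 1", "7 2 8 1")

# n-butane, heavy atoms only (united-atom)
butane_ligand <- function() {
  txt <- c(
    "@<TRIPOS>MOLECULE", "butane", " 4 3 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "1 C1 0.000 0.000 0.000 C.3 1 LIG 0.0",
    "2 C2 1.540 0.000 0.000 C.3 1 LIG 0.0",
    "3 C3 2.053 1.452 0.000 C.3 1 LIG 0.0",
    "4 C4 3.593 1.452 0.100 C.3 1 LIG 0.0",
    "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 1", "3 3 4 1")
  parse_mol2(txt)
}

benzene_mol2 <- function() {
  ang <- 2 * pi * (0:5) / 6
  at <- sprintf("%d C%d %.3f %.3f 0.000 C.ar 1 LIG 0.0", 1:6,
                1:6, 1.39 * cos(ang), 1.39 * sin(ang))
  bd <- sprintf("%d %d %d ar", 1:6, 1:6, c(2:6, 1))
  c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM", at, "@<TRIPOS>BOND", bd)
}

# 3-residue synthetic peptide backbone (Gly-Gly-Gly-like): 4 heavy atoms per
# residue (N, CA, C, O) = 12 heavy atoms
peptide_pdb <- function() {
  tmpl <- "ATOM  %5d %4s GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  lines <- character(0); i <- 0
  for (r in 1:3) {
    for (a in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      i <- i + 1
      lines <- c(lines, sprintf(tmpl, i, sprintf(" %-3s", a[1]), r,
                                3.5 * r + i %% 4, 1.2 * (i %% 3), 0.8 * i,
                                1, 10, a[2]))
    }
  }
  c(lines, "END")
}

single_carbon_receptor <- function(at = c(0, 0, 0)) {
  structure(data.frame(name = "C1", resid = "LIG", resno = 1, element = "C",
                       x = at[1], y = at[2], z = at[3], charge = 0,
                       atom_type = "C", hbond_role = "none",
                       stringsAsFactors = FALSE),
            class = c("receptor", "data.frame"))
}

planted_9 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lig <- make_chain_ligand(9)
      box <- binding_box(c(0, 0, 0), c(65, 65, 65), 0.375)
      cache <<- c(make_planted_complex(lig, box, seed = 3), list(box = box))
    }
    cache
  }
})
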