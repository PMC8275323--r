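# Molecular graph templates of the 20 proteinogenic L-amino acids, kekulized,
# with explicit hydrogens only on stereocentres. Each entry holds the atom
# elements, the bond list (single/double/triple), tetrahedral centres with
# their reference neighbour order and parity tag, and the backbone atom
# indices used to condense residues into a peptide (amide N, alpha carbon,
# carbonyl C, carbonyl O, and the hydroxyl O removed at each peptide bond).
# Stereo parities follow the standard L (2S; 2S,3R for Thr; 2S,3S for Ile)
# configurations.
.aa_graph_templates <- list(
  A = list(
    elements = c("N", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 2, 4, 1, 4, 5, 2, 4, 6, 1, 2, 7, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 4, 7))),
    n_amide = 1, ca = 2, c_carbonyl = 4, o_carbonyl = 5, o_hydroxyl = 6
  ),
  C = list(
    elements = c("N", "C", "C", "S", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 2, 5, 1, 5, 6, 2, 5, 7, 1, 2, 8, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 5, 8))),
    n_amide = 1, ca = 2, c_carbonyl = 5, o_carbonyl = 6, o_hydroxyl = 7
  ),
  D = list(
    elements = c("N", "C", "C", "C", "O", "O", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 4, 6, 2, 2, 7, 1, 7, 8, 2, 7, 9, 1, 2, 10, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 7, 10))),
    n_amide = 1, ca = 2, c_carbonyl = 7, o_carbonyl = 8, o_hydroxyl = 9
  ),
  E = list(
    elements = c("N", "C", "C", "C", "C", "O", "O", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 5, 7, 2, 2, 8, 1, 8, 9, 2, 8, 10, 1, 2, 11, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 8, 11))),
    n_amide = 1, ca = 2, c_carbonyl = 8, o_carbonyl = 9, o_hydroxyl = 10
  ),
  F = list(
    elements = c("N", "C", "C", "C", "C", "C", "C", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 2, 5, 6, 1, 6, 7, 2, 7, 8, 1, 8, 9, 2, 2, 10, 1, 10, 11, 2, 10, 12, 1, 9, 4, 1, 2, 13, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 10, 13))),
    n_amide = 1, ca = 2, c_carbonyl = 10, o_carbonyl = 11, o_hydroxyl = 12
  ),
  G = list(
    elements = c("N", "C", "C", "O", "O"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 2, 3, 5, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(),
    n_amide = 1, ca = 2, c_carbonyl = 3, o_carbonyl = 4, o_hydroxyl = 5
  ),
  H = list(
    elements = c("N", "C", "C", "C", "C", "N", "C", "N", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 2, 5, 6, 1, 6, 7, 2, 7, 8, 1, 2, 9, 1, 9, 10, 2, 9, 11, 1, 8, 4, 1, 2, 12, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 9, 12))),
    n_amide = 1, ca = 2, c_carbonyl = 9, o_carbonyl = 10, o_hydroxyl = 11
  ),
  I = list(
    elements = c("N", "C", "C", "C", "C", "C", "C", "O", "O", "H", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 3, 5, 1, 5, 6, 1, 2, 7, 1, 7, 8, 2, 7, 9, 1, 2, 10, 1, 3, 11, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 7, 10)), list(atom = 3, tag = "@@", nbrs = c(2, 4, 5, 11))),
    n_amide = 1, ca = 2, c_carbonyl = 7, o_carbonyl = 8, o_hydroxyl = 9
  ),
  K = list(
    elements = c("N", "C", "C", "C", "C", "C", "N", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 6, 7, 1, 2, 8, 1, 8, 9, 2, 8, 10, 1, 2, 11, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 8, 11))),
    n_amide = 1, ca = 2, c_carbonyl = 8, o_carbonyl = 9, o_hydroxyl = 10
  ),
  L = list(
    elements = c("N", "C", "C", "C", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 4, 6, 1, 2, 7, 1, 7, 8, 2, 7, 9, 1, 2, 10, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 7, 10))),
    n_amide = 1, ca = 2, c_carbonyl = 7, o_carbonyl = 8, o_hydroxyl = 9
  ),
  M = list(
    elements = c("N", "C", "C", "C", "S", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 2, 7, 1, 7, 8, 2, 7, 9, 1, 2, 10, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 7, 10))),
    n_amide = 1, ca = 2, c_carbonyl = 7, o_carbonyl = 8, o_hydroxyl = 9
  ),
  N = list(
    elements = c("N", "C", "C", "C", "N", "O", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 4, 6, 2, 2, 7, 1, 7, 8, 2, 7, 9, 1, 2, 10, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 7, 10))),
    n_amide = 1, ca = 2, c_carbonyl = 7, o_carbonyl = 8, o_hydroxyl = 9
  ),
  P = list(
    elements = c("N", "C", "C", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 6, 7, 2, 6, 8, 1, 5, 1, 1, 5, 9, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 5, tag = "@@", nbrs = c(4, 6, 1, 9))),
    n_amide = 1, ca = 5, c_carbonyl = 6, o_carbonyl = 7, o_hydroxyl = 8
  ),
  Q = list(
    elements = c("N", "C", "C", "C", "C", "N", "O", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 5, 7, 2, 2, 8, 1, 8, 9, 2, 8, 10, 1, 2, 11, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 8, 11))),
    n_amide = 1, ca = 2, c_carbonyl = 8, o_carbonyl = 9, o_hydroxyl = 10
  ),
  R = list(
    elements = c("N", "C", "C", "C", "C", "N", "C", "N", "N", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 6, 7, 2, 7, 8, 1, 7, 9, 1, 2, 10, 1, 10, 11, 2, 10, 12, 1, 2, 13, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 10, 13))),
    n_amide = 1, ca = 2, c_carbonyl = 10, o_carbonyl = 11, o_hydroxyl = 12
  ),
  S = list(
    elements = c("N", "C", "C", "O", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 2, 5, 1, 5, 6, 2, 5, 7, 1, 2, 8, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 5, 8))),
    n_amide = 1, ca = 2, c_carbonyl = 5, o_carbonyl = 6, o_hydroxyl = 7
  ),
  T = list(
    elements = c("N", "C", "C", "C", "O", "C", "O", "O", "H", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 3, 5, 1, 2, 6, 1, 6, 7, 2, 6, 8, 1, 2, 9, 1, 3, 10, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 6, 9)), list(atom = 3, tag = "@@", nbrs = c(2, 4, 5, 10))),
    n_amide = 1, ca = 2, c_carbonyl = 6, o_carbonyl = 7, o_hydroxyl = 8
  ),
  V = list(
    elements = c("N", "C", "C", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 3, 5, 1, 2, 6, 1, 6, 7, 2, 6, 8, 1, 2, 9, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 6, 9))),
    n_amide = 1, ca = 2, c_carbonyl = 6, o_carbonyl = 7, o_hydroxyl = 8
  ),
  W = list(
    elements = c("N", "C", "C", "C", "C", "N", "C", "C", "C", "C", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 2, 5, 6, 1, 6, 7, 1, 7, 8, 2, 8, 9, 1, 9, 10, 2, 10, 11, 1, 11, 12, 2, 2, 13, 1, 13, 14, 2, 13, 15, 1, 12, 4, 1, 12, 7, 1, 2, 16, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 13, 16))),
    n_amide = 1, ca = 2, c_carbonyl = 13, o_carbonyl = 14, o_hydroxyl = 15
  ),
  Y = list(
    elements = c("N", "C", "C", "C", "C", "C", "C", "O", "C", "C", "C", "O", "O", "H"),
    bonds = matrix(c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 2, 5, 6, 1, 6, 7, 2, 7, 8, 1, 7, 9, 1, 9, 10, 2, 2, 11, 1, 11, 12, 2, 11, 13, 1, 10, 4, 1, 2, 14, 1), ncol = 3, byrow = TRUE,
      dimnames = list(NULL, c("from", "to", "order"))),
    chiral = list(list(atom = 2, tag = "@@", nbrs = c(1, 3, 11, 14))),
    n_amide = 1, ca = 2, c_carbonyl = 11, o_carbonyl = 12, o_hydroxyl = 13
  )
)
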