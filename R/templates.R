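# Embedded standard nucleobase geometries in the standard reference frame
# (Tsukuba convention): base plane at z = 0, x toward the major groove,
# y toward the reference-strand backbone, origin at the frame origin used
# by mid-frame helical-parameter decompositions. Units angstrom. These
# coordinates are the single source of truth shared by the frame-fitting
# code and the synthetic-geometry builders.

.base_templates <- local({
  A <- rbind(
    `C1'` = c(-2.479, 5.346, 0.000),
    N9    = c(-1.291, 4.498, 0.000),
    C8    = c( 0.024, 4.897, 0.000),
    N7    = c( 0.877, 3.902, 0.000),
    C5    = c( 0.071, 2.771, 0.000),
    C6    = c( 0.369, 1.398, 0.000),
    N6    = c( 1.611, 0.909, 0.000),
    N1    = c(-0.668, 0.532, 0.000),
    C2    = c(-1.912, 1.023, 0.000),
    N3    = c(-2.320, 2.290, 0.000),
    C4    = c(-1.267, 3.124, 0.000))
  G <- rbind(
    `C1'` = c(-2.477, 5.399, 0.000),
    N9    = c(-1.289, 4.551, 0.000),
    C8    = c( 0.023, 4.962, 0.000),
    N7    = c( 0.870, 3.969, 0.000),
    C5    = c( 0.071, 2.833, 0.000),
    C6    = c( 0.424, 1.460, 0.000),
    O6    = c( 1.554, 0.955, 0.000),
    N1    = c(-0.700, 0.641, 0.000),
    C2    = c(-1.999, 1.087, 0.000),
    N2    = c(-2.949, 0.139, 0.000),
    N3    = c(-2.342, 2.364, 0.000),
    C4    = c(-1.265, 3.177, 0.000))
  C <- rbind(
    `C1'` = c(-2.477, 5.402, 0.000),
    N1    = c(-1.285, 4.542, 0.000),
    C2    = c(-1.472, 3.158, 0.000),
    O2    = c(-2.628, 2.709, 0.000),
    N3    = c(-0.391, 2.344, 0.000),
    C4    = c( 0.837, 2.868, 0.000),
    N4    = c( 1.875, 2.027, 0.000),
    C5    = c( 1.056, 4.275, 0.000),
    C6    = c(-0.023, 5.068, 0.000))
  T <- rbind(
    `C1'` = c(-2.481, 5.354, 0.000),
    N1    = c(-1.284, 4.500, 0.000),
    C2    = c(-1.462, 3.135, 0.000),
    O2    = c(-2.562, 2.608, 0.000),
    N3    = c(-0.298, 2.407, 0.000),
    C4    = c( 0.994, 2.897, 0.000),
    O4    = c( 1.944, 2.119, 0.000),
    C5    = c( 1.106, 4.338, 0.000),
    C7    = c( 2.466, 4.961, 0.000),
    C6    = c(-0.024, 5.057, 0.000))
  lapply(list(A = A, C = C, G = G, T = T), function(m) {
    colnames(m) <- c("x", "y", "z")
    m
  })
})

.purine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
.pyrimidine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")

#' Standard base template coordinates
#'
#' Returns the embedded standard-reference-frame coordinates of one of the
#' four canonical deoxyribonucleobases (plus the C1' sugar attachment atom).
#' The base lies in the z = 0 plane of its own reference frame.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"` (one-letter residue codes
#'   `DA`/`DC`/`DG`/`DT` are also accepted).
#' @return a numeric matrix (atoms x 3) with atom-name rownames.
#' @export
#' @examples
#' head(base_template("G"))
base_template <- function(base) {
  key <- toupper(sub("^D", "", base))
  if (!key %in% names(.base_templates)) {
    stop("unknown base type: ", base)
  }
  .base_templates[[key]]
}

is_purine <- function(base) toupper(sub("^D", "", base)) %in% c("A", "G")

ring_atom_names <- function(base) {
  if (is_purine(base)) .purine_ring else .pyrimidine_ring
}

# Watson-Crick complement of a one-letter base code.
complement_base <- function(base) {
  c(A = "T", T = "A", G = "C", C = "G")[[toupper(sub("^D", "", base))]]
}

#' Idealized planar-intercalator template
#'
#' A rigid model ligand exercising the geometry the pose and mode analyses
#' depend on: three fused six-membered "anthraquinone" rings A/B/C in the
#' z = 0 plane (ring centers along x, C on the negative side), a compact
#' four-atom pseudo-daunosamine group whose centroid sits off the ring
#' plane (negative z by default, i.e. sugar pointing "down"), two anchor
#' atoms, and a charged amine atom. Atom names encode the group: `A1..A6`,
#' `B1..B6`, `C1..C6`, `S1..S4`, `K1..K2`, `N1L`.
#'
#' @return list with `coords` (atoms x 3 matrix, angstrom, rownames = atom
#'   names) and `definition`, a [ligand_definition()] referencing those
#'   names with `residue_name = "LIG"`.
#' @export
ligand_template <- function() {
  hex <- function(cx) {
    ang <- (0:5) * pi / 3
    cbind(cx + 1.4 * cos(ang), 1.4 * sin(ang), 0)
  }
  ringC <- hex(-2.4)
  ringB <- hex(0)
  ringA <- hex(2.4)
  sugar_c <- c(3.2, 1.2, -1.6)
  sugar <- sweep(rbind(c(0.5, 0, 0), c(-0.5, 0, 0),
                       c(0, 0.5, -0.4), c(0, -0.5, 0.4)), 2, sugar_c, `+`)
  anchors <- rbind(c(3.8, -0.7, 0.4), c(4.2, 0.4, 0.2))
  amine <- matrix(c(3.6, 2.2, -2.2), 1, 3)
  coords <- rbind(ringA, ringB, ringC, sugar, anchors, amine)
  rownames(coords) <- c(paste0("A", 1:6), paste0("B", 1:6), paste0("C", 1:6),
                        paste0("S", 1:4), paste0("K", 1:2), "N1L")
  colnames(coords) <- c("x", "y", "z")
  def <- ligand_definition(
    residue_name = "LIG",
    ring_A_atoms = paste0("A", 1:6),
    ring_B_atoms = paste0("B", 1:6),
    ring_C_atoms = paste0("C", 1:6),
    daunosamine_atoms = paste0("S", 1:4),
    anchor_atoms = paste0("K", 1:2),
    amine_atom = "N1L")
  list(coords = coords, definition = def)
}
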