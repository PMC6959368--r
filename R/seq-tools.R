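AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Charge profile of a protein sequence
#'
#' Counts charged residues and the net charge under the convention standard
#' for solubility-tag engineering at neutral storage pH: D and E count -1,
#' K and R count +1, histidine is neutral, termini are ignored. The residue
#' sets are configurable.
#'
#' @param seq an amino-acid string (one-letter, uppercase; the 20 canonical
#'   residues plus X), or a named character vector of such strings.
#' @param negative,positive residue sets counted as -1 / +1.
#' @return For a single sequence, a list with `n_charged` and `net_charge`;
#'   for several, a data.frame with columns `id`, `n_charged`, `net_charge`.
#' @examples
#' charge_profile("DDK")   # 3 charged, net -1
#' @export
charge_profile <- function(seq, negative = c("D", "E"),
                           positive = c("K", "R")) {
  if (length(seq) > 1L) {
    out <- lapply(seq, charge_profile, negative = negative,
                  positive = positive)
    return(data.frame(id = names(seq) %||% as.character(seq_along(seq)),
                      n_charged = vapply(out, `[[`, numeric(1), "n_charged"),
                      net_charge = vapply(out, `[[`, numeric(1), "net_charge"),
                      row.names = NULL))
  }
  stopifnot(is.character(seq), nchar(seq) > 0L)
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% c(AA20, "X"))
  if (length(bad))
    stop("invalid residue '", res[bad[1]], "' at position ", bad[1])
  n_neg <- sum(res %in% negative)
  n_pos <- sum(res %in% positive)
  list(n_charged = n_neg + n_pos, net_charge = n_pos - n_neg)
}

#' Percent identity from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap penalties
#' (open 10, extend 0.5 - the conventional protein settings), via
#' `Biostrings::pairwiseAlignment`. Identity is the number of identical
#' aligned positions divided by the total number of alignment columns
#' (including gap columns), times 100. Identity figures are
#' method-sensitive, so the settings used are returned alongside the value.
#'
#' @param a,b amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties.
#' @param substitution substitution matrix name (default `"BLOSUM62"`).
#' @return List with `identity` (percent), `n_matches`, `alignment_length`,
#'   and `settings`.
#' @export
pairwise_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                              substitution = "BLOSUM62") {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend)
  len <- Biostrings::nchar(Biostrings::alignedPattern(aln))
  list(identity = Biostrings::nmatch(aln) / len * 100,
       n_matches = Biostrings::nmatch(aln),
       alignment_length = len,
       settings = list(substitution = substitution, gap_open = gap_open,
                       gap_extend = gap_extend, type = "global"))
}

#' Poisson-corrected evolutionary distance
#'
#' Corrects the observed proportion of differing aligned sites p for
#' multiple substitutions: d = -ln(1 - p). Strictly increasing and convex
#' on [0, 1); d ~ p for small p.
#'
#' @param p proportion(s) of differing sites, 0 <= p < 1.
#' @return Corrected distance(s).
#' @examples
#' poisson_distance(0.5)  # log(2)
#' @export
poisson_distance <- function(p) {
  if (!is.numeric(p) || anyNA(p)) stop("p must be numeric without NA")
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 1)) stop("p >= 1: distance saturated (undefined)")
  -log(1 - p)
}

#' Poisson-corrected distance matrix from aligned sequences
#'
#' Computes pairwise p-distances (proportion of differing sites) from a set
#' of equal-length aligned sequences and applies the Poisson correction.
#' Gap handling: `"pairwise"` deletion ignores, per pair, columns with a gap
#' in either sequence; `"complete"` deletion drops columns containing a gap
#' in any sequence before any comparison.
#'
#' @param aligned named character vector of aligned sequences (equal
#'   lengths; `-` for gaps).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric distance matrix with zero diagonal, labelled by the
#'   sequence names.
#' @export
poisson_dist_matrix <- function(aligned, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- length(aligned)
  if (n < 2L) stop("need at least two sequences")
  if (length(unique(nchar(aligned))) != 1L)
    stop("aligned sequences must have equal length")
  labs <- names(aligned) %||% paste0("seq", seq_len(n))
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  if (deletion == "complete") {
    keep <- colSums(mat == "-") == 0
    if (!any(keep)) stop("no gap-free columns under complete deletion")
    mat <- mat[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) stop("no comparable sites for ", labs[i], " vs ", labs[j])
    p <- mean(mat[i, ok] != mat[j, ok])
    d[i, j] <- d[j, i] <- poisson_distance(p)
  }
  d
}

#' Neighbor-Joining tree
#'
#' Classical Neighbor-Joining (Saitou-Nei) on a distance matrix: at each
#' step the pair minimizing Q(i,j) = (n-2) d(i,j) - r_i - r_j is joined
#' (ties broken deterministically toward the lowest row/column index),
#' branch lengths follow the standard three-point formulas and are clamped
#' at zero. NJ reconstructs additive (tree-metric) distances exactly.
#'
#' @param dm symmetric numeric matrix with zero diagonal and row/column
#'   labels (e.g. from [poisson_dist_matrix]), at least 3 taxa.
#' @return An unrooted `ape::phylo` tree with branch lengths; write it with
#'   `ape::write.tree`.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("Neighbor-Joining needs at least 3 taxa")
  if (ncol(dm) != n || !isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (any(!is.finite(dm))) stop("distances must be finite")
  if (any(diag(dm) != 0)) stop("diagonal must be zero")
  labs <- rownames(dm) %||% paste0("t", seq_len(n))
  # active nodes carried as newick subtree strings
  nodes <- labs
  d <- dm

  bl <- function(x) sprintf("%.10g", max(x, 0))
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest-index tie-break: first minimum in column-major order with i<j
    q[lower.tri(q, diag = TRUE)] <- Inf
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    newn <- sprintf("(%s:%s,%s:%s)", nodes[i], bl(vi), nodes[j], bl(vj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newn)
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], bl(v1), nodes[2], bl(v2), nodes[3], bl(v3))
  ape::read.tree(text = nwk)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning a named
#' character vector (uppercased).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
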