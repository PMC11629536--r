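# Morgan (ECFP-style) count fingerprints, molecules, Tanimoto similarity.

#' Fingerprint configuration
#'
#' Circular (Morgan) count fingerprints: hashed atom environments up to a
#' given radius, folded into a fixed-length count vector. The defaults (radius
#' 3, length 2048, counted) correspond to ECFP6-style 2048-position count
#' vectors; desk-scale experiment profiles may reduce both for speed.
#'
#' @param radius maximum environment radius (bonds); `>= 0`.
#' @param length number of positions the hashed identifiers are folded into.
#' @param counted keep environment counts (`TRUE`) or clip to presence bits.
#' @return an object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(radius = 3L, length = 2048L, counted = TRUE) {
  radius <- as.integer(radius); length <- as.integer(length)
  if (is.na(radius) || radius < 0L) stop_molhitl("radius must be >= 0")
  if (is.na(length) || length <= 0L) stop_molhitl("length must be > 0")
  structure(list(radius = radius, length = length, counted = isTRUE(counted)),
            class = "fingerprint_config")
}

fp_cfg_key <- function(cfg) sprintf("%d.%d.%d", cfg$radius, cfg$length, cfg$counted)

# initial Morgan atom invariant
atom_invariants <- function(mol) {
  deg <- integer(length(mol$elem))
  for (k in seq_along(mol$bfrom)) {
    deg[mol$bfrom[k]] <- deg[mol$bfrom[k]] + 1L
    deg[mol$bto[k]] <- deg[mol$bto[k]] + 1L
  }
  ecode <- match(mol$elem, .ORGANIC)
  as.integer(ecode * 100000L + deg * 10000L + mol$hcount * 1000L +
             (mol$charge + 5L) * 100L + as.integer(mol$arom) * 10L +
             as.integer(mol$ring_atom))
}

morgan_identifiers <- function(mol, radius) {
  n <- length(mol$elem)
  nbrs <- vector("list", n); bord <- vector("list", n); bidx <- vector("list", n)
  for (k in seq_along(mol$bfrom)) {
    i <- mol$bfrom[k]; j <- mol$bto[k]
    code <- bond_rank_code(mol, k)
    nbrs[[i]] <- c(nbrs[[i]], j - 1L); nbrs[[j]] <- c(nbrs[[j]], i - 1L)
    bord[[i]] <- c(bord[[i]], code); bord[[j]] <- c(bord[[j]], code)
    bidx[[i]] <- c(bidx[[i]], k - 1L); bidx[[j]] <- c(bidx[[j]], k - 1L)
  }
  for (a in seq_len(n)) {
    if (is.null(nbrs[[a]])) { nbrs[[a]] <- integer(0); bord[[a]] <- integer(0); bidx[[a]] <- integer(0) }
    nbrs[[a]] <- as.integer(nbrs[[a]]); bord[[a]] <- as.integer(bord[[a]])
    bidx[[a]] <- as.integer(bidx[[a]])
  }
  cpp_morgan_ids(atom_invariants(mol), nbrs, bord, bidx, as.integer(radius))
}

#' Morgan count fingerprint of a molecule
#'
#' @param smiles a single SMILES string.
#' @param cfg a [fingerprint_config()].
#' @return integer vector of length `cfg$length` with nonnegative counts
#'   (or presence bits when `cfg$counted` is `FALSE`).
#' @export
ecfp_count <- function(smiles, cfg = fingerprint_config()) {
  stopifnot(inherits(cfg, "fingerprint_config"))
  canon <- canonicalize(smiles[1L])
  key <- paste0(canon, "|", fp_cfg_key(cfg))
  hit <- cache_get("fp", key)
  if (!is.null(hit)) return(hit)
  ids <- morgan_identifiers(mol_of(canon), cfg$radius)
  idx <- as.integer(ids %% cfg$length) + 1L
  fp <- tabulate(idx, nbins = cfg$length)
  if (!cfg$counted) fp <- as.integer(fp > 0L)
  cache_set("fp", key, fp)
  fp
}

# fingerprints for a vector of SMILES as an n x D matrix (cached per molecule)
fingerprint_matrix <- function(smiles, cfg = fingerprint_config()) {
  out <- matrix(0L, nrow = length(smiles), ncol = cfg$length)
  for (i in seq_along(smiles)) out[i, ] <- ecfp_count(smiles[i], cfg)
  rownames(out) <- smiles
  out
}

#' Construct a molecule record
#'
#' Bundles the canonical SMILES, the count fingerprint and the scaffold key of
#' a molecule; the unit of data handled throughout the package.
#'
#' @param smiles a single SMILES string.
#' @param cfg a [fingerprint_config()].
#' @return an object of class `molecule` with fields `smiles` (canonical),
#'   `fingerprint` and `scaffold_key`.
#' @export
as_molecule <- function(smiles, cfg = fingerprint_config()) {
  canon <- canonicalize(smiles[1L])
  structure(list(smiles = canon, fingerprint = ecfp_count(canon, cfg),
                 scaffold_key = scaffold_key(canon)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$smiles, "\n")
  cat("  scaffold:", if (nzchar(x$scaffold_key)) x$scaffold_key else "(acyclic)", "\n")
  cat("  fingerprint: length", length(x$fingerprint),
      "| set positions", sum(x$fingerprint > 0), "\n")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' Fingerprints are binarized to presence bits first (counts feed the
#' predictor; bits feed similarity, following distribution-benchmark
#' convention). Returns `|a & b| / |a | b|`, with 0 for two empty vectors.
#'
#' @param fp_a,fp_b nonnegative numeric vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop_molhitl("fingerprint length mismatch (%d vs %d)", length(fp_a), length(fp_b))
  a <- fp_a > 0; b <- fp_b > 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# all-pairs Tanimoto between rows of two presence matrices
tanimoto_cross <- function(A, B) {
  A <- (A > 0) * 1; B <- (B > 0) * 1
  inter <- A %*% t(B)
  na <- rowSums(A); nb <- rowSums(B)
  uni <- outer(na, nb, "+") - inter
  out <- ifelse(uni > 0, inter / uni, 0)
  out
}
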