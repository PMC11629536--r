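# Deterministic fixture library (scaffold x substituent enumeration) and
# SMI / CSV readers and writers.
#
# The library stands in for a trained generative model's proposal space: a
# combinatorial assembly of ring scaffolds and substituents gives a few
# thousand valid, unique molecules spanning many scaffold keys, without any
# external data. Enumeration is fixed; a seed only shuffles the order.

fixture_scaffolds_one <- function() c(
  "c1ccc({R1})cc1",        # benzene
  "c1cc({R1})sc1",         # thiophene
  "c1cc({R1})oc1",         # furan
  "c1ccnc({R1})c1",        # pyridine
  "C1CCC({R1})CC1",        # cyclohexane
  "C1CCN({R1})CC1",        # piperidine (N-substituted)
  "C1CCC({R1})C1",         # cyclopentane
  "c1ccc2cc({R1})ccc2c1"   # naphthalene
)

fixture_scaffolds_two <- function() c(
  "c1cc({R1})cc({R2})c1",          # benzene, meta
  "c1cc({R1})ccc1{R2}",            # benzene, para
  "c1cc({R1})nc({R2})c1",          # pyridine
  "c1nc({R1})cc({R2})n1",          # pyrimidine
  "C1CC({R1})N({R2})CC1",          # piperidine, C + N
  "c1cc({R1})ccc1-c1ccc({R2})cc1", # biphenyl
  "C1COC({R1})C({R2})N1",          # morpholine
  "c1oc({R1})cc1{R2}",             # furan
  "c1sc({R1})cc1{R2}",             # thiophene
  "C1CC({R1})CCC1{R2}",            # cyclohexane
  "c1ccc2oc({R1})c({R2})c2c1",     # benzofuran
  "C1CN({R1})CCN1{R2}",            # piperazine
  "c1cnc({R1})c({R2})n1"           # pyrazine
)

fixture_substituents <- function() c(
  "", "C", "CC", "CCC", "C(C)C", "CCCC", "O", "OC", "OCC", "CO", "CCO",
  "N", "NC", "N(C)C", "C#N", "C=C", "F", "Cl", "Br", "C(F)(F)F",
  "C(=O)C", "C(=O)O", "C(=O)N", "S", "SC", "[N+](=O)[O-]"
)

fill_template <- function(template, r1, r2 = NULL) {
  fill_one <- function(s, slot, sub) {
    if (nzchar(sub)) {
      s <- gsub(sprintf("\\{%s\\}", slot), sub, s)
    } else {
      s <- gsub(sprintf("\\(\\{%s\\}\\)", slot), "", s, perl = TRUE)
      s <- gsub(sprintf("\\{%s\\}", slot), "", s)
    }
    s
  }
  out <- fill_one(template, "R1", r1)
  if (!is.null(r2)) out <- fill_one(out, "R2", r2)
  out
}

# full enumeration, canonicalized and deduplicated; cached per session
fixture_enumeration <- function() {
  hit <- cache_get("library", "base")
  if (!is.null(hit)) return(hit)
  subs <- fixture_substituents()
  raw <- character(0)
  for (tpl in fixture_scaffolds_one())
    for (s in subs) raw <- c(raw, fill_template(tpl, s))
  for (tpl in fixture_scaffolds_two())
    for (s1 in subs) for (s2 in subs)
      raw <- c(raw, fill_template(tpl, s1, s2))
  canon <- unique(canonicalize(raw))
  canon <- sort(canon, method = "radix")
  cache_set("library", "base", canon)
  canon
}

#' Deterministic fixture molecule library
#'
#' Enumerates a combinatorial scaffold-by-substituent library of valid, unique
#' molecules and returns `n` of them in a seeded random order. The same seed
#' always yields the same list. Stands in for a generative model's proposal
#' space in tests and desk-scale experiments.
#'
#' @param seed integer seed controlling the shuffle.
#' @param n number of molecules requested.
#' @return character vector of `n` unique canonical SMILES.
#' @examples
#' lib <- fixture_library(seed = 7, n = 50)
#' length(unique(lib)) == 50
#' @export
fixture_library <- function(seed, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop_molhitl("n must be >= 0")
  base <- fixture_enumeration()
  if (n > length(base))
    stop_molhitl("requested %d molecules but the fixture library enumerates only %d",
                 n, length(base))
  if (n == 0L) return(character(0))
  base[sample_stream(length(base), n, derive_seed(seed, 104729))]
}

# ---- file formats -----------------------------------------------------------

#' Read and write SMI files
#'
#' SMI files carry one SMILES per line with an optional tab-separated name;
#' lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @param canonical canonicalize on read?
#' @return `read_smi`: character vector of SMILES (names attached when the
#'   file carries them).
#' @export
read_smi <- function(path, canonical = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, character(1), 1L)
  nm <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", character(1))
  if (canonical) smiles <- canonicalize(smiles)
  if (any(nzchar(nm))) names(smiles) <- nm
  smiles
}

#' @rdname read_smi
#' @param smiles character vector of SMILES (names written as a second column
#'   when present).
#' @export
write_smi <- function(smiles, path) {
  nm <- names(smiles)
  lines <- if (is.null(nm)) smiles else
    ifelse(nzchar(nm), paste(smiles, nm, sep = "\t"), smiles)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write molecule tables (CSV)
#'
#' CSV files with a mandatory `smiles` column and optional `label` and
#' `weight` columns; `#` comment lines are ignored.
#'
#' @param path file path.
#' @param canonical canonicalize the smiles column on read?
#' @return a data.frame with at least a `smiles` column.
#' @export
read_molecule_csv <- function(path, canonical = FALSE) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df))
    stop_molhitl("'%s' has no 'smiles' column", path)
  if (canonical) df$smiles <- canonicalize(df$smiles)
  df
}

#' @rdname read_molecule_csv
#' @param df data.frame with a `smiles` column.
#' @export
write_molecule_csv <- function(df, path) {
  stopifnot(is.data.frame(df), "smiles" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
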