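# Canonical SMILES generation (Morgan-rank based) and Murcko-type scaffolds.
#
# Canonical form: atom ranks from iterative invariant refinement (element,
# degree, hydrogen count, charge, aromaticity, ring membership), ties broken
# by deterministically splitting the lowest tied class; the output string is a
# DFS over the graph visiting neighbors in rank order. Tests pin this form by
# round-trip identity (canonicalize twice == once), not by string constants.

bond_rank_code <- function(mol, k) if (mol$barom[k]) 4L else mol$border[k]

canonical_ranks <- function(mol) {
  n <- length(mol$elem)
  if (n == 1L) return(1L)
  nbr <- vector("list", n)
  bcode <- vector("list", n)
  for (k in seq_along(mol$bfrom)) {
    i <- mol$bfrom[k]; j <- mol$bto[k]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    code <- bond_rank_code(mol, k)
    bcode[[i]] <- c(bcode[[i]], code); bcode[[j]] <- c(bcode[[j]], code)
  }
  deg <- lengths(nbr)
  # all string sorts use radix (C collation) so ranks are locale-independent
  key <- sprintf("%s|%d|%d|%d|%d|%d", mol$elem, deg, mol$hcount,
                 mol$charge, as.integer(mol$arom), as.integer(mol$ring_atom))
  rank <- match(key, sort(unique(key), method = "radix"))

  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(a) {
        nb <- sprintf("%02d.%09d", bcode[[a]], rank[nbr[[a]]])
        paste0(sprintf("%09d", rank[a]), "|",
               paste(sort(nb, method = "radix"), collapse = ","))
      }, character(1))
      new <- match(key, sort(unique(key), method = "radix"))
      if (length(unique(new)) == length(unique(rank))) return(new)
      rank <- new
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    # split the lowest tied class; tied atoms are (near-universally in
    # chemistry-sized graphs) automorphic, so the member choice is inert
    tied <- which(rank == min(rank[duplicated(rank) | duplicated(rank, fromLast = TRUE)]))
    rank <- rank * 2L
    rank[tied[1L]] <- rank[tied[1L]] - 1L
    rank <- refine(match(rank, sort(unique(rank))))
  }
  rank
}

# hydrogen count a plain (bracket-free) atom token would imply
implied_hcount <- function(mol, a) {
  used <- 0; narom <- 0L
  for (k in seq_along(mol$bfrom)) {
    if (mol$bfrom[k] != a && mol$bto[k] != a) next
    used <- used + if (mol$barom[k]) 1 else mol$border[k]
    if (mol$barom[k]) narom <- narom + 1L
  }
  used <- used + (narom > 0L) * (mol$elem[a] %in% c("C", "N", "B", "P"))
  vs <- .VALENCE[[mol$elem[a]]]
  v <- vs[vs >= used][1L]
  if (is.na(v)) return(NA_integer_)
  as.integer(v - used)
}

atom_token <- function(mol, a) {
  sym <- if (mol$arom[a]) tolower(mol$elem[a]) else mol$elem[a]
  plain_ok <- mol$charge[a] == 0L &&
    identical(implied_hcount(mol, a), mol$hcount[a])
  if (plain_ok) return(sym)
  h <- mol$hcount[a]
  hstr <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
  q <- mol$charge[a]
  qstr <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
          else sprintf("%+d", q)
  paste0("[", sym, hstr, qstr, "]")
}

bond_token <- function(mol, k) {
  if (mol$barom[k]) return("")
  o <- mol$border[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl junction)
  if (mol$arom[mol$bfrom[k]] && mol$arom[mol$bto[k]]) "-" else ""
}

write_canonical <- function(mol) {
  n <- length(mol$elem)
  ranks <- canonical_ranks(mol)
  nbr <- vector("list", n)
  for (k in seq_along(mol$bfrom)) {
    nbr[[mol$bfrom[k]]] <- rbind(nbr[[mol$bfrom[k]]], c(mol$bto[k], k))
    nbr[[mol$bto[k]]] <- rbind(nbr[[mol$bto[k]]], c(mol$bfrom[k], k))
  }
  # pass 1: DFS in output order, assigning ring-closure digits
  visited <- logical(n)
  used_bond <- logical(length(mol$bfrom))
  closures <- vector("list", n)   # per atom: rbind(digit, bond)
  children <- vector("list", n)   # per atom: rbind(child, bond)
  digit <- 0L
  order_nbrs <- function(a) {
    if (is.null(nbr[[a]])) return(NULL)
    m <- nbr[[a]][order(ranks[nbr[[a]][, 1L]]), , drop = FALSE]
    m
  }
  start <- which.min(ranks)
  stack <- list(list(a = start, parent_bond = 0L))
  visited[start] <- TRUE
  # iterative DFS replicating recursion order
  dfs <- function(a) {
    for (r in seq_len(NROW(order_nbrs(a)))) {
      row <- order_nbrs(a)[r, ]
      b <- row[1L]; k <- row[2L]
      if (used_bond[k]) next
      if (visited[b]) {
        used_bond[k] <<- TRUE
        digit <<- digit + 1L
        closures[[a]] <<- rbind(closures[[a]], c(digit, k))
        closures[[b]] <<- rbind(closures[[b]], c(digit, k))
      } else {
        used_bond[k] <<- TRUE
        visited[b] <<- TRUE
        children[[a]] <<- rbind(children[[a]], c(b, k))
        dfs(b)
      }
    }
  }
  dfs(start)

  digit_token <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
  emit <- function(a) {
    out <- atom_token(mol, a)
    cl <- closures[[a]]
    if (!is.null(cl)) {
      cl <- cl[order(cl[, 1L]), , drop = FALSE]
      for (r in seq_len(nrow(cl)))
        out <- paste0(out, bond_token(mol, cl[r, 2L]), digit_token(cl[r, 1L]))
    }
    ch <- children[[a]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (r in seq_len(nc)) {
        part <- paste0(bond_token(mol, ch[r, 2L]), emit(ch[r, 1L]))
        out <- paste0(out, if (r < nc) paste0("(", part, ")") else part)
      }
    }
    out
  }
  emit(start)
}

#' Canonicalize SMILES strings
#'
#' Maps each SMILES string to the package's canonical form, so that two
#' notations of the same molecule yield identical strings. Canonicalization is
#' idempotent; invalid SMILES raise an error naming the offending string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(smiles) {
  vapply(smiles, function(s) {
    hit <- cache_get("canon", s)
    if (!is.null(hit)) return(hit)
    out <- write_canonical(parse_smiles(s))
    cache_set("canon", s, out)
    cache_set("canon", out, out)  # canonical form is a fixed point
    out
  }, character(1), USE.NAMES = FALSE)
}

# parse with memoization on the canonical string
mol_of <- function(smiles) {
  canon <- canonicalize(smiles)
  hit <- cache_get("mol", canon)
  if (!is.null(hit)) return(hit)
  mol <- parse_smiles(canon)
  cache_set("mol", canon, mol)
  mol
}

# induced subgraph on `atoms` (indices); implicit hydrogens re-resolved
mol_subgraph <- function(mol, atoms) {
  atoms <- sort(atoms)
  idx <- match(seq_along(mol$elem), atoms)
  keep <- which(mol$bfrom %in% atoms & mol$bto %in% atoms)
  sub <- list(elem = mol$elem[atoms], arom = mol$arom[atoms],
              charge = mol$charge[atoms], hexp = mol$hexp[atoms],
              bfrom = idx[mol$bfrom[keep]], bto = idx[mol$bto[keep]],
              border = mol$border[keep], barom = mol$barom[keep],
              smiles = mol$smiles)
  ringb <- ring_bonds(length(sub$elem), sub$bfrom, sub$bto)
  ring_atom <- logical(length(sub$elem))
  ring_atom[c(sub$bfrom[ringb], sub$bto[ringb])] <- TRUE
  sub$ring_atom <- ring_atom
  sub$ring_bond <- ringb
  sub$hcount <- resolve_hcounts(sub)
  sub
}

#' Murcko-type scaffold of a molecule
#'
#' Returns the ring framework (ring systems plus linkers, with atoms attached
#' by multiple bonds retained) as a canonical SMILES string, or the empty
#' string for acyclic molecules. Used as the bucket key of the diversity
#' filter memory.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of scaffold SMILES ("" for acyclic molecules).
#' @examples
#' scaffold_key("c1ccccc1CCO")  # benzene
#' scaffold_key("CCO")          # ""
#' @export
scaffold_key <- function(smiles) {
  vapply(smiles, function(s) {
    canon <- canonicalize(s)
    hit <- cache_get("scaf", canon)
    if (!is.null(hit)) return(hit)
    mol <- mol_of(canon)
    out <- scaffold_of(mol)
    cache_set("scaf", canon, out)
    out
  }, character(1), USE.NAMES = FALSE)
}

scaffold_of <- function(mol) {
  if (!any(mol$ring_atom)) return("")
  n <- length(mol$elem)
  keep <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    for (k in seq_along(mol$bfrom)) {
      if (keep[mol$bfrom[k]] && keep[mol$bto[k]]) {
        deg[mol$bfrom[k]] <- deg[mol$bfrom[k]] + 1L
        deg[mol$bto[k]] <- deg[mol$bto[k]] + 1L
      }
    }
    drop <- keep & deg <= 1L & !mol$ring_atom
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # retain atoms attached to the framework by a multiple bond (e.g. =O)
  repeat {
    added <- FALSE
    for (k in seq_along(mol$bfrom)) {
      if (mol$border[k] < 2L || mol$barom[k]) next
      i <- mol$bfrom[k]; j <- mol$bto[k]
      if (keep[i] && !keep[j]) { keep[j] <- TRUE; added <- TRUE }
      else if (keep[j] && !keep[i]) { keep[i] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  write_canonical(mol_subgraph(mol, which(keep)))
}
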