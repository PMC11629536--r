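# SMILES parsing and molecular-graph utilities.
#
# The package carries its own small SMILES toolkit: a parser for the organic
# subset plus bracket atoms (H counts and formal charges), aromatic lowercase
# notation, branches and ring-closure digits. Stereochemistry, isotopes and
# multi-fragment SMILES are out of scope. The internal molecule representation
# is a graph: element / aromatic flag / charge / resolved hydrogen count per
# atom, and an edge table with bond orders (aromatic bonds flagged).

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("B", "C", "N", "O", "P", "S")
# default valence and maximum allowed (hypervalent S/P accepted)
.VALENCE <- list(B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
                 F = 1L, Cl = 1L, Br = 1L, I = 1L)

smiles_error <- function(smiles, why) {
  stop(sprintf("invalid SMILES '%s': %s", smiles, why), call. = FALSE)
}

# Parse a bracket atom body (between '[' and ']'), e.g. "nH", "N+", "O-".
parse_bracket <- function(body, smiles) {
  rest <- body
  take <- function(pattern) {
    m <- regmatches(rest, regexpr(pattern, rest))
    if (length(m) && nzchar(m)) rest <<- substring(rest, nchar(m) + 1L) else m <- ""
    m
  }
  if (nzchar(take("^[0-9]+"))) smiles_error(smiles, "isotopes are not supported")
  elem <- take("^(Cl|Br|[BCNOPSFI]|[bcnops])")
  if (!nzchar(elem)) smiles_error(smiles, sprintf("unsupported bracket atom [%s]", body))
  arom <- elem %in% c("b", "c", "n", "o", "p", "s")
  if (arom) elem <- toupper(elem)
  if (nzchar(take("^@+"))) smiles_error(smiles, "stereochemistry is not supported")
  h <- 0L
  if (nzchar(take("^H"))) {
    d <- take("^[0-9]+")
    h <- if (nzchar(d)) as.integer(d) else 1L
  }
  charge <- 0L
  sign <- take("^[+-]+")
  if (nzchar(sign)) {
    s <- if (substring(sign, 1L, 1L) == "+") 1L else -1L
    d <- take("^[0-9]+")
    charge <- if (nzchar(d)) s * as.integer(d) else s * nchar(sign)
  }
  if (nzchar(rest)) smiles_error(smiles, sprintf("unsupported bracket atom [%s]", body))
  list(elem = elem, arom = arom, h = h, charge = charge)
}

# Parse one SMILES string into an internal molecule graph.
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("invalid SMILES: expected a single non-empty string", call. = FALSE)

  elem <- character(); arom <- logical(); charge <- integer(); hexp <- integer()
  bfrom <- integer(); bto <- integer(); border <- integer(); barom_sym <- logical()
  bexplicit <- logical()

  prev <- NA_integer_
  stack <- integer()
  pending <- NA_character_
  rings <- list()   # digit label -> list(atom, bond symbol)

  add_atom <- function(e, a, h, q) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- a
    charge[length(charge) + 1L] <<- q
    hexp[length(hexp) + 1L] <<- h
    length(elem)
  }
  add_bond <- function(i, j, sym) {
    if (i == j) smiles_error(smiles, "ring closure to the same atom")
    if (any((bfrom == i & bto == j) | (bfrom == j & bto == i)))
      smiles_error(smiles, "duplicate bond")
    k <- length(bfrom) + 1L
    bfrom[k] <<- i; bto[k] <<- j
    if (is.na(sym)) {
      border[k] <<- 1L; barom_sym[k] <<- FALSE; bexplicit[k] <<- FALSE
    } else {
      border[k] <<- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L)
      barom_sym[k] <<- sym == ":"
      bexplicit[k] <<- TRUE
    }
  }
  on_atom <- function(e, a = FALSE, h = NA_integer_, q = 0L) {
    idx <- add_atom(e, a, h, q)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NA_character_
    prev <<- idx
  }
  close_ring <- function(label) {
    if (!is.null(rings[[label]])) {
      open <- rings[[label]]
      sym <- pending
      if (is.na(sym)) sym <- open$sym
      else if (!is.na(open$sym) && open$sym != sym)
        smiles_error(smiles, "conflicting ring-closure bond symbols")
      add_bond(open$atom, prev, sym)
      rings[[label]] <<- NULL
    } else {
      rings[[label]] <<- list(atom = prev, sym = pending)
    }
    pending <<- NA_character_
  }

  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "(") {
      if (is.na(prev)) smiles_error(smiles, "branch before any atom")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (!length(stack)) smiles_error(smiles, "unbalanced parentheses")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch
    } else if (ch %in% c("/", "\\")) {
      smiles_error(smiles, "stereochemistry is not supported")
    } else if (ch == ".") {
      smiles_error(smiles, "disconnected fragments are not supported")
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        smiles_error(smiles, "malformed %nn ring closure")
      if (is.na(prev)) smiles_error(smiles, "ring closure before any atom")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 2L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) smiles_error(smiles, "ring closure before any atom")
      close_ring(ch)
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) smiles_error(smiles, "unclosed bracket atom")
      b <- parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""), smiles)
      on_atom(b$elem, b$arom, b$h, b$charge)
      i <- j
    } else if (two %in% c("Cl", "Br")) {
      on_atom(two)
      i <- i + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      on_atom(ch)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      on_atom(toupper(ch), a = TRUE)
    } else {
      smiles_error(smiles, sprintf("unexpected character '%s'", ch))
    }
    i <- i + 1L
  }
  if (length(stack)) smiles_error(smiles, "unbalanced parentheses")
  if (length(rings)) smiles_error(smiles, "unclosed ring bond")
  if (!length(elem)) smiles_error(smiles, "no atoms")

  mol <- list(elem = elem, arom = arom, charge = charge, hexp = hexp,
              bfrom = bfrom, bto = bto, border = border,
              barom = logical(length(bfrom)), hcount = integer(length(elem)),
              smiles = smiles)
  finalize_mol(mol, barom_sym, bexplicit)
}

# Resolve aromatic bonds, ring membership, implicit hydrogens; validate.
finalize_mol <- function(mol, barom_sym, bexplicit) {
  nb <- length(mol$bfrom)
  # default (unwritten) bond between two aromatic atoms is aromatic
  if (nb) {
    mol$barom <- barom_sym | (!bexplicit & mol$arom[mol$bfrom] & mol$arom[mol$bto])
  } else {
    mol$barom <- logical(0)
  }

  if (length(mol$elem) > 1L) {
    comp <- graph_components(length(mol$elem), mol$bfrom, mol$bto)
    if (max(comp) > 1L) smiles_error(mol$smiles, "disconnected fragments are not supported")
  }

  ringb <- ring_bonds(length(mol$elem), mol$bfrom, mol$bto)
  ring_atom <- logical(length(mol$elem))
  ring_atom[c(mol$bfrom[ringb], mol$bto[ringb])] <- TRUE
  mol$ring_atom <- ring_atom
  mol$ring_bond <- ringb

  if (any(mol$barom & !ringb))
    smiles_error(mol$smiles, "aromatic bond outside a ring")
  if (any(mol$arom & !ring_atom))
    smiles_error(mol$smiles, "aromatic atom outside a ring")

  mol$hcount <- resolve_hcounts(mol)
  mol
}

# Implicit hydrogen resolution; bracket atoms keep their explicit count.
resolve_hcounts <- function(mol) {
  n <- length(mol$elem)
  used <- numeric(n)
  narom <- integer(n)
  for (k in seq_along(mol$bfrom)) {
    i <- mol$bfrom[k]; j <- mol$bto[k]
    o <- if (mol$barom[k]) 1 else mol$border[k]
    used[i] <- used[i] + o; used[j] <- used[j] + o
    if (mol$barom[k]) { narom[i] <- narom[i] + 1L; narom[j] <- narom[j] + 1L }
  }
  # the aromatic system consumes one extra valence on C/N-type atoms
  # (pyridine-type n: no H); divalent aromatic O/S take none
  used <- used + (narom > 0L) * (mol$elem %in% c("C", "N", "B", "P"))
  h <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(mol$hexp[a])) { h[a] <- mol$hexp[a]; next }
    vs <- .VALENCE[[mol$elem[a]]]
    v <- vs[vs >= used[a]][1L]
    if (is.na(v))
      smiles_error(mol$smiles, sprintf("valence of %s atom exceeded", mol$elem[a]))
    h[a] <- as.integer(v - used[a])
  }
  h
}

# ---- graph utilities (molecule-sized graphs; plain R) ----------------------

graph_adjacency <- function(n, bfrom, bto) {
  adj <- vector("list", n)
  for (k in seq_along(bfrom)) {
    adj[[bfrom[k]]] <- c(adj[[bfrom[k]]], bto[k])
    adj[[bto[k]]] <- c(adj[[bto[k]]], bfrom[k])
  }
  adj
}

graph_components <- function(n, bfrom, bto) {
  adj <- graph_adjacency(n, bfrom, bto)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in adj[[a]]) if (!comp[b]) { comp[b] <- cur; queue <- c(queue, b) }
    }
  }
  comp
}

# Bonds that lie on a cycle (non-bridges), via iterative DFS lowlink.
ring_bonds <- function(n, bfrom, bto) {
  m <- length(bfrom)
  if (m == 0L) return(logical(0))
  inc <- vector("list", n)  # incident (neighbor, bond) pairs
  for (k in seq_len(m)) {
    inc[[bfrom[k]]] <- rbind(inc[[bfrom[k]]], c(bto[k], k))
    inc[[bto[k]]] <- rbind(inc[[bto[k]]], c(bfrom[k], k))
  }
  disc <- integer(n); low <- integer(n)
  bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root]) next
    stack <- list(list(a = root, pe = 0L, i = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      a <- fr$a
      if (is.null(inc[[a]]) || fr$i > nrow(inc[[a]])) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pf <- stack[[length(stack)]]
          low[pf$a] <- min(low[pf$a], low[a])
          if (low[a] > disc[pf$a]) bridge[fr$pe] <- TRUE
        }
        next
      }
      b <- inc[[a]][fr$i, 1L]; e <- inc[[a]][fr$i, 2L]
      stack[[length(stack)]]$i <- fr$i + 1L
      if (e == fr$pe) next
      if (disc[b]) {
        low[a] <- min(low[a], disc[b])
      } else {
        timer <- timer + 1L
        disc[b] <- low[b] <- timer
        stack[[length(stack) + 1L]] <- list(a = b, pe = e, i = 1L)
      }
    }
  }
  !bridge
}

# Approximate smallest set of smallest rings: for every ring bond, the
# shortest cycle through it; deduplicated and greedily selected up to the
# cyclomatic number. Used for the ring-size census (long-cycle penalty).
mol_rings <- function(mol) {
  n <- length(mol$elem)
  ringb <- which(mol$ring_bond)
  if (!length(ringb)) return(list())
  cyclomatic <- length(mol$bfrom) - n + 1L
  adj <- vector("list", n)
  for (k in seq_along(mol$bfrom)) {
    adj[[mol$bfrom[k]]] <- rbind(adj[[mol$bfrom[k]]], c(mol$bto[k], k))
    adj[[mol$bto[k]]] <- rbind(adj[[mol$bto[k]]], c(mol$bfrom[k], k))
  }
  cand <- list()
  for (e in ringb) {
    s <- mol$bfrom[e]; t <- mol$bto[e]
    # BFS shortest path s -> t avoiding bond e
    prev <- integer(n); seen <- logical(n)
    queue <- s; seen[s] <- TRUE
    while (length(queue) && !seen[t]) {
      a <- queue[1L]; queue <- queue[-1L]
      for (r in seq_len(nrow(adj[[a]]))) {
        b <- adj[[a]][r, 1L]; k <- adj[[a]][r, 2L]
        if (k == e || seen[b]) next
        seen[b] <- TRUE; prev[b] <- a
        queue <- c(queue, b)
      }
    }
    if (!seen[t]) next
    path <- t
    while (path[1L] != s) path <- c(prev[path[1L]], path)
    cand[[length(cand) + 1L]] <- sort(path)
  }
  cand <- unique(cand)
  cand <- cand[order(lengths(cand))]
  out <- list()
  covered <- logical(length(mol$bfrom))
  for (ring in cand) {
    if (length(out) >= cyclomatic) break
    members <- which((mol$bfrom %in% ring) & (mol$bto %in% ring))
    if (all(covered[members])) next
    covered[members] <- TRUE
    out[[length(out) + 1L]] <- ring
  }
  out
}
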