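#' Hydrogen-depleted molecular graph
#'
#' A `molgraph` is the substrate of every descriptor in the package: a
#' connected, hydrogen-depleted coloured graph. Atoms carry an element symbol,
#' an aromaticity flag, a formal charge and an implicit-hydrogen count; bonds
#' carry an integer order (1, 2, 3) plus an aromaticity flag (aromatic bonds
#' are stored with their Kekule order so that valence arithmetic stays exact).
#' Atom indices are 1-based.
#'
#' @name molgraph
#' @section Fields:
#' \describe{
#'   \item{element}{character vector of element symbols}
#'   \item{aromatic}{logical vector, atom aromaticity}
#'   \item{charge}{integer vector of formal charges}
#'   \item{hcount}{integer vector of implicit hydrogens}
#'   \item{bonds}{data.frame with columns `i`, `j`, `order`, `aromatic`}
#' }
NULL

ORGANIC_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

new_molgraph <- function(element, aromatic, charge, hcount, bonds) {
  structure(list(
    element = element,
    aromatic = aromatic,
    charge = as.integer(charge),
    hcount = as.integer(hcount),
    bonds = bonds,
    n = length(element)
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds, %d ring(s)>\n",
              x$n, nrow(x$bonds), cyclomatic_number(x)))
  comp <- table(x$element)
  cat("  formula-ish:", paste0(names(comp), comp, collapse = " "),
      sprintf(" (+%dH implicit)\n", sum(x$hcount)))
  invisible(x)
}

#' Number of heavy atoms
#' @param g a [molgraph]
#' @return integer atom count
#' @export
n_atoms <- function(g) g$n

#' Heavy-atom degree vector
#' @param g a [molgraph]
#' @return integer vector of heavy-neighbour counts
#' @export
degrees <- function(g) {
  d <- integer(g$n)
  t1 <- tabulate(g$bonds$i, g$n)
  t2 <- tabulate(g$bonds$j, g$n)
  t1 + t2
}

#' Adjacency list of a molecular graph
#' @param g a [molgraph]
#' @return list of integer neighbour vectors
#' @export
adjacency_list <- function(g) {
  adj <- vector("list", g$n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Cyclomatic number (number of independent rings)
#' @param g a [molgraph]
#' @return integer ring count `q - n + 1`
#' @export
cyclomatic_number <- function(g) nrow(g$bonds) - g$n + 1L

bond_orders_of <- function(g, i) {
  sel <- g$bonds$i == i | g$bonds$j == i
  g$bonds$order[sel]
}

#' Per-atom hybridisation-ish class
#'
#' Classifies heavy atoms as `"sp3"`, `"sp2"` (one double bond or aromatic) or
#' `"sp"` (triple or two double bonds). Used by the Kier alpha corrections and
#' the constitutional counts.
#' @param g a [molgraph]
#' @return character vector
#' @export
hybridization <- function(g) {
  out <- character(g$n)
  for (i in seq_len(g$n)) {
    sel <- g$bonds$i == i | g$bonds$j == i
    ords <- g$bonds$order[sel]
    arom <- any(g$bonds$aromatic[sel])
    if (any(ords == 3) || sum(ords == 2) >= 2) out[i] <- "sp"
    else if (arom || any(ords == 2)) out[i] <- "sp2"
    else out[i] <- "sp3"
  }
  out
}

# ---------------------------------------------------------------------------
# SMILES tokenizer + parser
# ---------------------------------------------------------------------------

smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  toks <- list(); i <- 1; n <- length(chars)
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("SMILES parse error: unmatched '[' at position ", i)
      toks[[length(toks) + 1]] <- list(type = "atom",
                                       text = paste(chars[i:j], collapse = ""),
                                       pos = i)
      i <- j + 1
    } else if (i < n && paste0(ch, chars[i + 1]) %in% two_letter) {
      toks[[length(toks) + 1]] <- list(type = "atom", text = paste0(ch, chars[i + 1]), pos = i)
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      toks[[length(toks) + 1]] <- list(type = "atom", text = ch, pos = i)
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":")) {
      toks[[length(toks) + 1]] <- list(type = "bond", text = ch, pos = i)
      i <- i + 1
    } else if (ch %in% c("/", "\\")) {
      # stereo bond decorations: treated as single bonds (no descriptor in
      # scope distinguishes geometric isomers)
      i <- i + 1
    } else if (ch == "(") {
      toks[[length(toks) + 1]] <- list(type = "open", text = ch, pos = i)
      i <- i + 1
    } else if (ch == ")") {
      toks[[length(toks) + 1]] <- list(type = "close", text = ch, pos = i)
      i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      toks[[length(toks) + 1]] <- list(type = "ring", text = ch, pos = i)
      i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n) stop("SMILES parse error: bad % ring closure at position ", i)
      toks[[length(toks) + 1]] <- list(type = "ring",
                                       text = paste(chars[(i + 1):(i + 2)], collapse = ""),
                                       pos = i)
      i <- i + 3
    } else if (ch == ".") {
      stop("SMILES parse error: disconnected structures ('.') are rejected")
    } else {
      stop("SMILES parse error: unexpected token '", ch, "' at position ", i)
    }
  }
  toks
}

parse_bracket_atom <- function(text, pos) {
  m <- regmatches(text, regexec(
    "^\\[([0-9]*)([A-Z][a-z]?|[a-z]|\\*)(@{1,2}|@TH[12])?(H([0-9]*))?([+-][0-9]*|\\+\\+|--)?\\]$",
    text))[[1]]
  if (length(m) == 0)
    stop("SMILES parse error: unparseable bracket atom '", text, "' at position ", pos)
  sym <- m[3]
  aromatic <- sym == tolower(sym) && sym != "*"
  if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  hcount <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
  chg <- m[7]
  charge <- if (chg == "") 0L
  else if (chg == "+") 1L else if (chg == "-") -1L
  else if (chg == "++") 2L else if (chg == "--") -2L
  else as.integer(paste0(substr(chg, 1, 1), substring(chg, 2)))
  list(symbol = sym, aromatic = aromatic, hcount = hcount, charge = charge,
       explicit_h = TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, halogens), aromatic
#' lowercase atoms, bracket atoms with explicit H counts and charges, branches,
#' ring-bond closures (including `%nn`) and bond symbols `- = # :`.
#' Stereochemistry markers are accepted and discarded. Aromatic rings written
#' in lowercase are Kekulized internally so that every bond carries an integer
#' order; Kekule-written benzene rings are detected and flagged aromatic by a
#' simple Hueckel rule on isolated 6-rings (sufficient for the terpenoid
#' chemotypes this package targets).
#'
#' @param smiles a single SMILES string
#' @return a [molgraph]
#' @examples
#' g <- parse_smiles("CC(C)c1ccc(C)cc1O")  # carvacrol
#' n_atoms(g)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || !nzchar(smiles))
    stop("SMILES parse error: input must be a single non-empty string")
  toks <- smiles_tokens(smiles)

  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  hexp <- integer(0); has_exp_h <- logical(0)
  bi <- integer(0); bj <- integer(0); bord <- integer(0); barom <- logical(0)

  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_character_
  ring_open <- list()

  add_bond <- function(a, b, sym, either_arom) {
    if (a == b) stop("SMILES parse error: self-loop ring closure")
    if (is.na(sym)) {
      if (either_arom) { ord <- 1L; ar <- TRUE }
      else { ord <- 1L; ar <- FALSE }
    } else {
      ord <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L)
      ar <- sym == ":"
    }
    bi <<- c(bi, a); bj <<- c(bj, b); bord <<- c(bord, ord); barom <<- c(barom, ar)
  }

  for (tk in toks) {
    if (tk$type == "atom") {
      if (startsWith(tk$text, "[")) {
        at <- parse_bracket_atom(tk$text, tk$pos)
      } else {
        sym <- tk$text
        ar <- sym %in% c("b", "c", "n", "o", "p", "s")
        if (ar) sym <- toupper(sym)
        if (!sym %in% names(ORGANIC_VALENCE))
          stop("SMILES parse error: unknown element '", tk$text, "' at position ", tk$pos)
        at <- list(symbol = sym, aromatic = ar, hcount = 0L, charge = 0L,
                   explicit_h = FALSE)
      }
      element <- c(element, at$symbol); aromatic <- c(aromatic, at$aromatic)
      charge <- c(charge, at$charge); hexp <- c(hexp, at$hcount)
      has_exp_h <- c(has_exp_h, at$explicit_h)
      idx <- length(element)
      if (!is.na(prev)) {
        add_bond(prev, idx, pending, aromatic[prev] && at$aromatic)
      }
      prev <- idx; pending <- NA_character_
    } else if (tk$type == "bond") {
      pending <- tk$text
    } else if (tk$type == "open") {
      if (is.na(prev)) stop("SMILES parse error: branch with no preceding atom")
      stack <- c(stack, prev)
    } else if (tk$type == "close") {
      if (length(stack) == 0) stop("SMILES parse error: unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (tk$type == "ring") {
      if (is.na(prev)) stop("SMILES parse error: ring closure with no preceding atom")
      key <- tk$text
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, bond = pending)
      } else {
        op <- ring_open[[key]]
        sym <- if (!is.na(pending)) pending else op$bond
        add_bond(op$atom, prev, sym, aromatic[op$atom] && aromatic[prev])
        ring_open[[key]] <- NULL
      }
      pending <- NA_character_
    }
  }
  if (length(stack) > 0) stop("SMILES parse error: unmatched '('")
  open_left <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_left) > 0)
    stop("SMILES parse error: unclosed ring bond(s) ", paste(open_left, collapse = ", "))
  if (length(element) == 0) stop("SMILES parse error: no atoms")
  if (any(duplicated(cbind(pmin(bi, bj), pmax(bi, bj)))))
    stop("SMILES parse error: parallel bond")

  bonds <- data.frame(i = bi, j = bj, order = bord, aromatic = barom)
  # bonds between two aromatic atoms are aromatic even when written
  # with an implicit single bond inside a lowercase ring
  if (nrow(bonds) > 0)
    bonds$aromatic <- bonds$aromatic | (aromatic[bonds$i] & aromatic[bonds$j])

  g <- new_molgraph(element, aromatic, charge, hexp, bonds)
  if (!is_connected(g))
    stop("SMILES parse error: disconnected structure rejected")
  g <- kekulize(g)
  g <- perceive_aromaticity(g)
  # implicit hydrogens for organic-subset atoms without explicit H spec
  for (i in seq_len(g$n)) {
    if (!has_exp_h[i]) {
      val <- ORGANIC_VALENCE[[g$element[i]]]
      used <- sum(bond_orders_of(g, i))
      # neutral organic subset; charged atoms require bracket notation anyway
      g$hcount[i] <- max(0L, as.integer(val - used))
    }
  }
  validate_molgraph(g)
  g
}

is_connected <- function(g) {
  if (g$n == 1) return(TRUE)
  adj <- adjacency_list(g)
  seen <- logical(g$n); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# Assign Kekule orders to aromatic bonds via backtracking perfect matching on
# the aromatic subgraph (atoms that need exactly one formal double bond).
kekulize <- function(g) {
  arom_bonds <- which(g$bonds$aromatic & g$bonds$order == 1)
  if (length(arom_bonds) == 0) return(g)
  arom_atoms <- which(g$aromatic)
  # pi contributors: aromatic C needs one double bond; aromatic N with H or
  # aromatic O/S donate a lone pair and need none (pyrrole/furan style)
  needs <- rep(FALSE, g$n)
  for (i in arom_atoms) {
    el <- g$element[i]
    if (el == "C") needs[i] <- TRUE
    else if (el == "N") {
      # pyridine N (no H, degree 2) takes part in a double bond
      deg <- sum(g$bonds$i == i | g$bonds$j == i)
      hn <- g$hcount[i]
      needs[i] <- !(hn > 0 || deg == 3)
    } else needs[i] <- FALSE
  }
  cand <- arom_bonds[needs[g$bonds$i[arom_bonds]] & needs[g$bonds$j[arom_bonds]]]
  target <- which(needs)
  assign_dbl <- logical(length(cand))
  matched <- rep(FALSE, g$n)
  solve <- function(k) {
    if (all(matched[target])) return(TRUE)
    if (k > length(cand)) return(FALSE)
    b <- cand[k]; i <- g$bonds$i[b]; j <- g$bonds$j[b]
    if (!matched[i] && !matched[j]) {
      matched[i] <<- TRUE; matched[j] <<- TRUE; assign_dbl[k] <<- TRUE
      if (solve(k + 1)) return(TRUE)
      matched[i] <<- FALSE; matched[j] <<- FALSE; assign_dbl[k] <<- FALSE
    }
    solve(k + 1)
  }
  if (!solve(1))
    stop("SMILES parse error: cannot Kekulize aromatic system")
  g$bonds$order[cand[assign_dbl]] <- 2L
  g
}

# Simple Hueckel perception on isolated 6-rings written in Kekule form:
# a 6-cycle of carbons with alternating single/double bonds becomes aromatic.
perceive_aromaticity <- function(g) {
  if (cyclomatic_number(g) == 0) return(g)
  adj <- adjacency_list(g)
  bond_id <- function(a, b) which((g$bonds$i == a & g$bonds$j == b) |
                                  (g$bonds$i == b & g$bonds$j == a))
  seen_rings <- character(0)
  for (start in seq_len(g$n)) {
    # DFS for 6-cycles through `start`
    path <- integer(0)
    dfs <- function(v, depth) {
      path[depth] <<- v
      if (depth == 6) {
        if (start %in% adj[[v]]) {
          ring <- path[1:6]
          key <- paste(sort(ring), collapse = "-")
          if (!key %in% seen_rings) {
            seen_rings <<- c(seen_rings, key)
            check_ring(ring)
          }
        }
        return(invisible(NULL))
      }
      for (w in adj[[v]]) {
        if (w > start && !(w %in% path[seq_len(depth)])) dfs(w, depth + 1)
      }
    }
    check_ring <- function(ring) {
      if (!all(g$element[ring] == "C")) return(invisible(NULL))
      ords <- integer(6)
      for (k in 1:6) {
        a <- ring[k]; b <- ring[if (k == 6) 1 else k + 1]
        ords[k] <- g$bonds$order[bond_id(a, b)]
      }
      alt <- all(ords == c(1, 2, 1, 2, 1, 2)) || all(ords == c(2, 1, 2, 1, 2, 1))
      if (alt) {
        g$aromatic[ring] <<- TRUE
        for (k in 1:6) {
          a <- ring[k]; b <- ring[if (k == 6) 1 else k + 1]
          g$bonds$aromatic[bond_id(a, b)] <<- TRUE
        }
      }
      invisible(NULL)
    }
    dfs(start, 1)
  }
  g
}

validate_molgraph <- function(g) {
  stopifnot(nrow(g$bonds) == 0 || all(g$bonds$i != g$bonds$j))
  for (i in which(g$element == "C")) {
    used <- sum(bond_orders_of(g, i)) + g$hcount[i]
    if (used != 4 + g$charge[i] * 0)
      stop("valence error: carbon atom ", i, " has total bond order ", used)
  }
  invisible(g)
}

# ---------------------------------------------------------------------------
# Canonical SMILES emission
# ---------------------------------------------------------------------------

canonical_ranks <- function(g) {
  # Morgan-style iterative refinement on (element, degree, hcount, aromatic,
  # bond-order multiset), tie-broken deterministically.
  ords <- vapply(seq_len(g$n), function(i) {
    paste(sort(bond_orders_of(g, i)), collapse = "")
  }, character(1))
  inv <- paste(g$element, degrees(g), g$hcount, g$aromatic, g$charge, ords, sep = "|")
  rank <- match(inv, sort(unique(inv)))
  adj <- adjacency_list(g)
  for (it in seq_len(g$n)) {
    key <- vapply(seq_len(g$n), function(i) {
      paste(rank[i], paste(sort(rank[adj[[i]]]), collapse = ","), sep = ";")
    }, character(1))
    new_rank <- match(key, sort(unique(key)))
    if (identical(new_rank, rank)) break
    rank <- new_rank
  }
  rank
}

#' Emit a canonical SMILES string
#'
#' Deterministic emission from a canonical atom ranking (Morgan-style
#' refinement). The output is stable across input atom orderings of the same
#' graph; parse -> emit -> parse yields an isomorphic graph.
#'
#' @param g a [molgraph]
#' @return a SMILES string
#' @export
write_smiles <- function(g) {
  rank <- canonical_ranks(g)
  adj <- adjacency_list(g)
  bond_id <- function(a, b) which((g$bonds$i == a & g$bonds$j == b) |
                                  (g$bonds$i == b & g$bonds$j == a))
  visited <- logical(g$n)
  ring_count <- 0L
  ring_label <- list()   # per closure bond id -> digit
  closure_at <- vector("list", g$n)
  used_bond <- logical(nrow(g$bonds))
  tree_bond <- logical(nrow(g$bonds))

  # spanning DFS, mark ring-closure bonds
  order_children <- function(v) {
    nb <- adj[[v]]
    nb[order(rank[nb], nb)]
  }
  # first pass to place ring closure digits
  start <- which.min(rank * 1000 + seq_len(g$n))
  stack <- list(list(v = start, parent = NA))
  visited_p <- logical(g$n)
  dfs1 <- function(v, parent) {
    visited_p[v] <<- TRUE
    for (w in order_children(v)) {
      b <- bond_id(v, w)
      if (!is.na(parent) && w == parent && !used_bond[b]) { used_bond[b] <<- TRUE; next }
      if (visited_p[w]) {
        if (!used_bond[b]) {
          used_bond[b] <<- TRUE
          ring_count <<- ring_count + 1L
          ring_label[[as.character(b)]] <<- ring_count
          closure_at[[v]] <<- c(closure_at[[v]], b)
          closure_at[[w]] <<- c(closure_at[[w]], b)
        }
      } else {
        used_bond[b] <<- TRUE
        tree_bond[b] <<- TRUE
        dfs1(w, v)
      }
    }
  }
  dfs1(start, NA)

  atom_token <- function(i) {
    sym <- g$element[i]
    tok <- if (g$aromatic[i]) tolower(sym) else sym
    needs_bracket <- g$charge[i] != 0 || !sym %in% names(ORGANIC_VALENCE)
    if (!needs_bracket) {
      # check implicit-H agreement under organic subset rules
      val <- ORGANIC_VALENCE[[sym]]
      used <- sum(bond_orders_of(g, i))
      if (val - used != g$hcount[i]) needs_bracket <- TRUE
    }
    if (needs_bracket) {
      h <- if (g$hcount[i] > 0) paste0("H", ifelse(g$hcount[i] > 1, g$hcount[i], "")) else ""
      ch <- g$charge[i]
      cs <- if (ch == 0) "" else if (ch > 0) paste0("+", ifelse(ch > 1, ch, "")) else
        paste0("-", ifelse(ch < -1, -ch, ""))
      paste0("[", tok, h, cs, "]")
    } else tok
  }
  bond_token <- function(b) {
    if (g$bonds$aromatic[b]) return("")
    switch(g$bonds$order[b], "", "=", "#")
  }

  emit <- function(v, from_bond) {
    visited[v] <<- TRUE
    out <- if (is.na(from_bond)) atom_token(v) else paste0(bond_token(from_bond), atom_token(v))
    for (b in closure_at[[v]]) {
      lab <- ring_label[[as.character(b)]]
      other <- setdiff(c(g$bonds$i[b], g$bonds$j[b]), v)
      btok <- if (visited[other]) "" else bond_token(b)
      out <- paste0(out, btok, if (lab > 9) paste0("%", lab) else lab)
    }
    subs <- character(0)
    for (w in order_children(v)) {
      if (visited[w]) next
      b <- bond_id(v, w)
      if (!tree_bond[b]) next  # ring-closure bond, not a tree edge
      subs <- c(subs, emit(w, b))
    }
    if (length(subs) > 0) {
      k <- length(subs)
      if (k > 1) out <- paste0(out, paste0("(", subs[-k], ")", collapse = ""))
      out <- paste0(out, subs[k])
    }
    out
  }
  emit(start, NA)
}

#' Read a SMILES file
#'
#' One structure per line, optionally followed by a tab and a name. Empty
#' lines and `#` comments are skipped.
#'
#' @param path file path
#' @return data.frame with columns `smiles`, `name`
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty SMILES file: ", path)
  parts <- strsplit(lines, "\t")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write canonical SMILES to a file
#' @param graphs list of [molgraph] objects
#' @param path output path
#' @param names optional character vector of names (tab-separated column)
#' @return invisibly, the path
#' @export
write_smiles_file <- function(graphs, path, names = NULL) {
  smi <- vapply(graphs, write_smiles, character(1))
  lines <- if (is.null(names)) smi else paste(smi, names, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
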