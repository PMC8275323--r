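# Peptides are represented as explicit molecular graphs (kekulized, explicit
# hydrogens only on stereocentres) assembled from the residue templates in
# aa-templates.R. SMILES strings are written from the graph by depth-first
# traversal; because any traversal order yields a valid SMILES of the same
# molecule, randomizing the start atom and neighbour order gives the
# augmentation used for the epitope stream. Canonicalization is delegated to
# OpenBabel (via ChemmineOB), which also serves as the external validity
# check.

.ORGANIC_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L,
                      Cl = 1L, Br = 1L, I = 1L, B = 3L)

#' @keywords internal
smiles_string <- function(text, graph = NULL, canonical = FALSE) {
  structure(text, class = "smiles_string", graph = graph, canonical = canonical)
}

#' @export
print.smiles_string <- function(x, ...) {
  cat(sprintf("<smiles%s> %s\n", if (isTRUE(attr(x, "canonical"))) " (canonical)" else "",
              unclass(x)))
  invisible(x)
}

#' Assemble the molecular graph of a linear peptide
#'
#' Condenses the residue templates N-to-C: each peptide bond removes the
#' hydroxyl oxygen of the upstream carboxyl group (one water lost per bond,
#' together with an amine hydrogen that is implicit) and bonds the carbonyl
#' carbon to the downstream amide nitrogen. The free N-terminus and the
#' C-terminal acid are kept.
#'
#' @param seq Peptide sequence over the 20 standard amino acids, 1-50
#'   residues.
#' @param stereo Keep the L-alpha-carbon (and Thr/Ile side-chain)
#'   stereocentres (default `TRUE`).
#' @return A molecular graph: list with `elements`, `bonds` (from/to/order
#'   matrix) and `chiral` (list of tetrahedral centres).
#' @keywords internal
peptide_graph <- function(seq, stereo = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a single non-empty string")
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(res) > 50L) stop("peptides longer than 50 residues are not supported")
  bad <- setdiff(unique(res), names(.aa_graph_templates))
  if (length(bad))
    stop("non-standard residues cannot be converted to SMILES: ",
         paste(bad, collapse = ", "))
  n <- length(res)
  elements <- character(0)
  bonds <- NULL
  chiral <- list()
  offset <- integer(n)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- .aa_graph_templates[[res[i]]]
    offset[i] <- length(elements)
    elements <- c(elements, tpl$elements)
    b <- tpl$bonds
    b[, 1:2] <- b[, 1:2] + offset[i]
    bonds <- rbind(bonds, b)
    if (stereo) for (ch in tpl$chiral)
      chiral[[length(chiral) + 1L]] <-
        list(atom = ch$atom + offset[i], tag = ch$tag, nbrs = ch$nbrs + offset[i])
    info[[i]] <- list(n_amide = tpl$n_amide + offset[i],
                      c_carbonyl = tpl$c_carbonyl + offset[i],
                      o_hydroxyl = tpl$o_hydroxyl + offset[i])
  }
  drop_atoms <- integer(0)
  for (i in seq_len(n - 1L)) {
    drop_atoms <- c(drop_atoms, info[[i]]$o_hydroxyl)
    bonds <- rbind(bonds, c(info[[i]]$c_carbonyl, info[[i + 1L]]$n_amide, 1L))
  }
  if (length(drop_atoms)) {
    keep <- setdiff(seq_along(elements), drop_atoms)
    remap <- integer(length(elements))
    remap[keep] <- seq_along(keep)
    elements <- elements[keep]
    bonds <- bonds[!(bonds[, 1] %in% drop_atoms | bonds[, 2] %in% drop_atoms), ,
                   drop = FALSE]
    bonds[, 1:2] <- cbind(remap[bonds[, 1]], remap[bonds[, 2]])
    chiral <- lapply(chiral, function(ch)
      list(atom = remap[ch$atom], tag = ch$tag, nbrs = remap[ch$nbrs]))
  }
  list(elements = elements, bonds = bonds, chiral = chiral)
}

# adjacency list: for each atom, matrix of (neighbour, order)
#' @keywords internal
graph_adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- rep(list(NULL), n)
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds[r, 1]; j <- graph$bonds[r, 2]; o <- graph$bonds[r, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  adj
}

# Write a SMILES string from a molecular graph by depth-first traversal.
# `shuffle = TRUE` randomizes the start atom and the neighbour order (using
# the current RNG stream); the default order is deterministic. Tetrahedral
# tags are re-derived for the written neighbour order by permutation parity
# against the stored reference order.
#' @keywords internal
write_smiles <- function(graph, shuffle = FALSE) {
  n <- length(graph$elements)
  is_h <- graph$elements == "H"
  adj <- graph_adjacency(graph)
  chiral_of <- rep(list(NULL), n)
  for (ch in graph$chiral) chiral_of[[ch$atom]] <- ch
  heavy <- which(!is_h)
  start <- if (shuffle) heavy[sample.int(length(heavy), 1L)] else heavy[1L]

  visited <- logical(n)
  edge_used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  parent <- integer(n); parent_order <- integer(n)
  children <- rep(list(NULL), n)     # ordered child ids
  rings <- rep(list(NULL), n)        # ordered (edge key, other atom, order)
  hcount <- integer(n)
  order_seen <- integer(0)

  dfs <- function(a) {
    visited[a] <<- TRUE
    order_seen <<- c(order_seen, a)
    nb <- adj[[a]]
    if (is.null(nb)) return(invisible())
    idx <- seq_len(nrow(nb))
    if (shuffle && length(idx) > 1L) idx <- sample(idx)
    for (r in idx) {
      b <- nb[r, 1]; o <- nb[r, 2]
      if (is_h[b]) { hcount[a] <<- hcount[a] + 1L; next }
      key <- ekey(a, b)
      if (!is.null(edge_used[[key]])) next
      if (visited[b]) {
        edge_used[[key]] <- TRUE
        rings[[a]] <<- c(rings[[a]], list(list(key = key, other = b, order = o)))
        rings[[b]] <<- c(rings[[b]], list(list(key = key, other = a, order = o)))
      } else {
        edge_used[[key]] <- TRUE
        parent[b] <<- a; parent_order[b] <<- o
        children[[a]] <<- c(children[[a]], b)
        dfs(b)
      }
    }
    invisible()
  }
  dfs(start)
  if (!all(visited[heavy])) stop("disconnected molecular graph")

  bond_sym <- function(o) c("", "=", "#")[o]
  digit_of <- new.env(hash = TRUE, parent = emptyenv())
  free_digits <- 1:99
  render <- function(a) {
    ring_list <- rings[[a]]
    ring_txt <- ""
    ring_others <- integer(0)
    for (rg in ring_list) {
      d <- digit_of[[rg$key]]
      if (is.null(d)) {
        d <- free_digits[1L]
        free_digits <<- free_digits[-1L]
        digit_of[[rg$key]] <- d
      } else {
        free_digits <<- sort(c(free_digits, d))
      }
      ring_txt <- paste0(ring_txt, bond_sym(rg$order),
                         if (d > 9) sprintf("%%%02d", d) else d)
      ring_others <- c(ring_others, rg$other)
    }
    ch <- chiral_of[[a]]
    if (is.null(ch)) {
      atom_txt <- graph$elements[a]
      if (!atom_txt %in% names(.ORGANIC_VALENCE))
        stop("cannot write element without bracket support: ", atom_txt)
    } else {
      # written neighbour order: parent, explicit H, ring partners, children
      h_nbr <- if (hcount[a] > 0L) {
        nb <- adj[[a]]
        nb[is_h[nb[, 1]], 1][1L]
      }
      written <- c(if (parent[a] > 0L) parent[a], h_nbr, ring_others,
                   unlist(children[[a]]))
      perm <- match(written, ch$nbrs)
      if (anyNA(perm) || length(perm) != 4L)
        stop("chiral centre with inconsistent neighbour set")
      tag <- if (perm_parity(perm) == 1L) ch$tag
             else if (ch$tag == "@") "@@" else "@"
      atom_txt <- paste0("[", graph$elements[a], tag,
                         if (hcount[a] == 1L) "H"
                         else if (hcount[a] > 1L) paste0("H", hcount[a]), "]")
    }
    kids <- children[[a]]
    branch_txt <- ""
    if (length(kids)) {
      parts <- vapply(kids, function(b)
        paste0(bond_sym(parent_order[b]), render(b)), character(1))
      if (length(parts) > 1L)
        branch_txt <- paste0(paste0("(", parts[-length(parts)], ")", collapse = ""),
                             parts[length(parts)])
      else branch_txt <- parts
    }
    paste0(atom_txt, ring_txt, branch_txt)
  }
  render(start)
}

# parity of a permutation given as an integer vector: +1 even, -1 odd
#' @keywords internal
perm_parity <- function(p) {
  n <- length(p)
  swaps <- 0L
  for (i in seq_len(n - 1L)) {
    j <- which(p == i)
    if (j != i) {
      p[c(i, j)] <- p[c(j, i)]
      swaps <- swaps + 1L
    }
  }
  if (swaps %% 2L == 0L) 1L else -1L
}

#' Canonicalize a SMILES string
#'
#' Converts to OpenBabel's canonical SMILES form. Canonicalization is
#' idempotent and maps every valid SMILES of a molecule to the same string,
#' which makes it the reference for augmentation-invariance checks.
#'
#' @param s A SMILES string (plain character or `smiles_string`).
#' @return A canonical `smiles_string` (the molecular graph attribute, if
#'   present, is carried along).
#' @export
canonicalize_smiles <- function(s) {
  text <- as.character(s)
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = text)
  out <- strsplit(out, "[ \t\n]")[[1]][1]
  if (is.na(out) || !nzchar(out))
    stop("OpenBabel could not parse SMILES: ", text)
  smiles_string(out, graph = attr(s, "graph"), canonical = TRUE)
}

#' Canonicalize many SMILES strings in one OpenBabel call
#'
#' Vectorized companion of [canonicalize_smiles()]: the strings are
#' converted in a single batch, which is much faster than one call per
#' molecule.
#'
#' @param texts Character vector of SMILES strings.
#' @param chunk_size Molecules per OpenBabel call; the conversion scales
#'   badly with very large multi-molecule inputs, so big sets are processed
#'   in chunks of this size (default 100).
#' @return Character vector of canonical SMILES, same length and order.
#' @export
canonicalize_smiles_batch <- function(texts, chunk_size = 100L) {
  texts <- as.character(texts)
  if (!length(texts)) return(character(0))
  res <- rep(NA_character_, length(texts))
  for (s in seq(1L, length(texts), by = chunk_size)) {
    idx <- s:min(s + chunk_size - 1L, length(texts))
    # titles keep the output aligned with the input
    src <- paste(paste(texts[idx], seq_along(idx)), collapse = "\n")
    out <- ChemmineOB::convertFormat("SMI", "CAN", source = src)
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    for (p in parts) res[idx[as.integer(p[2])]] <- p[1]
  }
  if (anyNA(res))
    stop(sprintf("OpenBabel could not parse %d of %d SMILES", sum(is.na(res)),
                 length(texts)))
  res
}

#' Convert a peptide to its canonical SMILES
#'
#' Builds the linear peptide molecule (free N-terminus, C-terminal acid,
#' L-stereochemistry from the residue templates, one water condensed out
#' per peptide bond) and returns its canonical SMILES. The molecular graph
#' is attached as an attribute so that [augment_smiles()] can rewrite the
#' molecule without re-parsing.
#'
#' @param seq Peptide sequence (1-50 of the 20 standard amino acids).
#' @param stereo Include stereocentres (default `TRUE`); `FALSE` strips
#'   them.
#' @return A canonical `smiles_string`.
#' @examples
#' peptide_to_smiles("G")   # glycine, C2H5NO2
#' peptide_to_smiles("GG")  # glycylglycine, C4H8N2O3
#' @export
peptide_to_smiles <- function(seq, stereo = TRUE) {
  g <- peptide_graph(seq, stereo = stereo)
  canonicalize_smiles(smiles_string(write_smiles(g), graph = g))
}

#' Randomized SMILES augmentation
#'
#' Rewrites a molecule as a different -- but equally valid -- SMILES string
#' by restarting the traversal at a random atom with a random neighbour
#' order. The canonical form of the output always equals the canonical form
#' of the input: only the string representation changes, never the
#' molecule. Molecules created by this package carry their graph and are
#' rewritten directly; other input is parsed through OpenBabel first (which
#' drops stereocentres, so external stereo SMILES should be augmented from
#' a graph).
#'
#' @param s A `smiles_string` (or plain SMILES character).
#' @param rng_seed Seed for the randomized traversal.
#' @return A `smiles_string` with the same canonical form as `s`.
#' @export
augment_smiles <- function(s, rng_seed = 1L) {
  g <- attr(s, "graph")
  if (is.null(g)) g <- parse_smiles_graph(as.character(s))
  txt <- with_seed(rng_seed, write_smiles(g, shuffle = TRUE))
  smiles_string(txt, graph = g, canonical = FALSE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Round-trips through OpenBabel's SD format (via [ChemmineR::smiles2sdf()])
#' to obtain atoms and kekulized bonds. Stereochemistry and formal charges
#' are not retained.
#'
#' @param text A SMILES string.
#' @return A molecular graph as used by [augment_smiles()].
#' @keywords internal
parse_smiles_graph <- function(text) {
  # single-atom molecules (no bond block) confuse the SDF round trip
  if (grepl("^(Cl|Br|[BCNOSPFI])$", text))
    return(list(elements = text,
                bonds = matrix(integer(0), 0L, 3L,
                               dimnames = list(NULL, c("from", "to", "order"))),
                chiral = list()))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(text))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || ncol(bb) < 3L || nrow(bb) == 0L)
    matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("from", "to", "order")))
  else cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
  bonds <- bonds[bonds[, 1] > 0L & bonds[, 2] > 0L, , drop = FALSE]
  if (any(bonds[, 3] > 3L))
    stop("aromatic/query bond orders are not supported; supply kekulized SMILES")
  list(elements = elements, bonds = bonds, chiral = list())
}

# Molecular formula (Hill order) from a graph, counting implicit hydrogens
# from standard valences; used for reporting, not as the test oracle.
#' @keywords internal
graph_formula <- function(graph) {
  is_h <- graph$elements == "H"
  counts <- table(graph$elements[!is_h])
  nH <- sum(is_h)
  deg <- numeric(length(graph$elements))
  for (r in seq_len(nrow(graph$bonds))) {
    deg[graph$bonds[r, 1]] <- deg[graph$bonds[r, 1]] + graph$bonds[r, 3]
    deg[graph$bonds[r, 2]] <- deg[graph$bonds[r, 2]] + graph$bonds[r, 3]
  }
  for (a in which(!is_h)) {
    v <- .ORGANIC_VALENCE[[graph$elements[a]]]
    nH <- nH + max(0L, v - deg[a])
  }
  els <- sort(names(counts))
  els <- c(intersect(c("C"), els), setdiff(els, "C"))
  parts <- character(0)
  for (e in els) {
    parts <- c(parts, paste0(e, if (counts[[e]] > 1L) counts[[e]] else ""))
    if (e == "C" && nH > 0L)
      parts <- c(parts, paste0("H", if (nH > 1L) nH else ""))
  }
  if (!"C" %in% els && nH > 0L) parts <- c(parts, paste0("H", if (nH > 1L) nH else ""))
  paste(parts, collapse = "")
}
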