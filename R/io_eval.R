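# Structure readers/writers and structural evaluation metrics.
#
# Two plain-text structure formats are supported: a whitespace-separated
# "parent child" edge list ('#' comments allowed), and the BIF format of
# the Bayesian-network repositories, parsed for structure only (the
# conditional probability tables are ignored).

#' Read a directed structure from a file
#'
#' @param path File path.
#' @param format `"edgelist"` or `"bif"`; guessed from the extension by
#'   default.
#' @param names Optional full variable set (edge lists only): isolated
#'   variables cannot be inferred from edges alone.
#' @return Logical adjacency matrix with variable names as dimnames.
#' @export
read_structure <- function(path, format = c("auto", "edgelist", "bif"),
                           names = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bif$", path, ignore.case = TRUE)) "bif"
    else "edgelist"
  }
  g <- if (format == "bif") read_bif(path) else read_edgelist(path, names)
  if (!is_acyclic(g)) {
    cyc <- find_cycle(g)
    stop("structure in ", path, " is cyclic, e.g.: ",
         paste(rownames(g)[cyc], collapse = " -> "), call. = FALSE)
  }
  g
}

read_edgelist <- function(path, names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pairs <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(pairs) != 2L)
  if (length(bad)) {
    stop("malformed edge-list line ", bad[[1L]], " in ", path, call. = FALSE)
  }
  parent <- vapply(pairs, `[[`, character(1), 1L)
  child <- vapply(pairs, `[[`, character(1), 2L)
  vars <- if (is.null(names)) sort(unique(c(parent, child))) else names
  unknown <- setdiff(c(parent, child), vars)
  if (length(unknown)) {
    stop("unknown variable name: ", unknown[[1L]], call. = FALSE)
  }
  g <- empty_graph(length(vars), vars)
  g[cbind(match(parent, vars), match(child, vars))] <- TRUE
  g
}

# Structure-only BIF parser: collects "variable NAME" declarations and
# "probability ( CHILD | P1, P2, ... )" headers.
read_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vars <- regmatches(
    txt, gregexpr("variable[[:space:]]+([^[:space:]{]+)", txt)
  )[[1L]]
  vars <- sub("variable[[:space:]]+", "", vars)
  if (!length(vars)) {
    stop("no variable declarations found in ", path, call. = FALSE)
  }
  g <- empty_graph(length(vars), vars)
  probs <- regmatches(
    txt, gregexpr("probability[[:space:]]*\\(([^)]*)\\)", txt)
  )[[1L]]
  for (p in probs) {
    inner <- sub("^probability[[:space:]]*\\(", "", sub("\\)$", "", p))
    halves <- strsplit(inner, "\\|")[[1L]]
    child <- trimws(halves[[1L]])
    if (!child %in% vars) {
      stop("unknown variable name: ", child, call. = FALSE)
    }
    if (length(halves) > 1L) {
      parents <- trimws(strsplit(halves[[2L]], ",")[[1L]])
      unknown <- setdiff(parents, vars)
      if (length(unknown)) {
        stop("unknown variable name: ", unknown[[1L]], call. = FALSE)
      }
      g[cbind(match(parents, vars), match(child, vars))] <- TRUE
    }
  }
  g
}

# One directed cycle of a cyclic graph (vertex sequence), for diagnostics.
find_cycle <- function(g) {
  n <- nrow(g)
  colour <- integer(n) # 0 white, 1 grey, 2 black
  stack <- integer(0)
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    colour[v] <<- 1L
    stack <<- c(stack, v)
    for (w in which(g[v, ])) {
      if (colour[w] == 1L) {
        cyc <<- c(stack[which(stack == w)[[1L]]:length(stack)], w)
        return()
      }
      if (colour[w] == 0L) visit(w)
      if (!is.null(cyc)) return()
    }
    colour[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in seq_len(n)) if (colour[v] == 0L) visit(v)
  cyc
}

#' Write a structure as an edge list
#'
#' Lexicographic "parent child" lines.
#'
#' @param g Adjacency matrix with dimnames (or supply `names`).
#' @param path Output path.
#' @param names Optional variable names.
#' @export
write_edgelist <- function(g, path, names = NULL) {
  tb <- edges_tbl(g, names)
  writeLines(paste(tb$parent, tb$child), path)
  invisible(path)
}

align_graphs <- function(learned, truth) {
  if (!all(dim(learned) == dim(truth))) {
    stop("learned and true graphs have different dimensions", call. = FALSE)
  }
  ln <- rownames(learned)
  tn <- rownames(truth)
  if (!is.null(ln) && !is.null(tn) && !identical(ln, tn)) {
    if (!setequal(ln, tn)) {
      stop("learned and true graphs have different variable sets",
           call. = FALSE)
    }
    learned <- learned[tn, tn]
  }
  list(learned = learned, truth = truth)
}

#' Structural error counts
#'
#' Skeleton decomposition of the disagreement between a learned and a true
#' DAG: `ad` counts learned skeleton edges absent from the true skeleton
#' (added), `dd` true skeleton edges absent from the learned one (deleted),
#' and `rd` shared skeleton edges whose orientation disagrees (reversed).
#'
#' @param learned,truth Directed adjacency matrices over the same
#'   variables.
#' @return Named list `ad`, `dd`, `rd`.
#' @export
structural_errors <- function(learned, truth) {
  al <- align_graphs(learned, truth)
  skl <- al$learned | t(al$learned)
  skt <- al$truth | t(al$truth)
  both <- skl & skt
  list(
    ad = sum(skl & !skt) / 2L,
    dd = sum(skt & !skl) / 2L,
    rd = sum(both & al$learned & t(al$truth)) # i->j learned, j->i true
  )
}

#' Directed-edge F1 score
#'
#' Precision and recall over directed edges; a true positive requires the
#' exact orientation. F1 = 2PR/(P + R), 0 when P + R = 0.
#'
#' @inheritParams structural_errors
#' @return Named list `precision`, `recall`, `f1`.
#' @export
f1_score <- function(learned, truth) {
  al <- align_graphs(learned, truth)
  tp <- sum(al$learned & al$truth)
  nl <- sum(al$learned)
  nt <- sum(al$truth)
  p <- if (nl > 0) tp / nl else 0
  r <- if (nt > 0) tp / nt else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

#' Evaluate a learned structure against a reference
#'
#' Bundles the structural error counts, directed-edge precision/recall/F1
#' and, when data are supplied, the BIC of the learned structure and of the
#' reference ("standard") network (SBS) on those data.
#'
#' @inheritParams structural_errors
#' @param data Optional data (`data_matrix` or data frame) for the scores.
#' @param nll_factor Passed to [score_context()].
#' @return A one-row tibble: `ad`, `dd`, `rd`, `precision`, `recall`, `f1`,
#'   `learned_score`, `sbs`.
#' @export
evaluate_structure <- function(learned, truth, data = NULL,
                               nll_factor = 0.5) {
  se <- structural_errors(learned, truth)
  f <- f1_score(learned, truth)
  learned_score <- NA_real_
  sbs <- NA_real_
  if (!is.null(data)) {
    sctx <- score_context(data, nll_factor = nll_factor)
    al <- align_graphs(learned, truth)
    learned_score <- graph_score(sctx, al$learned)
    sbs <- graph_score(sctx, al$truth)
  }
  tibble(
    ad = se$ad, dd = se$dd, rd = se$rd,
    precision = f$precision, recall = f$recall, f1 = f$f1,
    learned_score = learned_score, sbs = sbs
  )
}
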