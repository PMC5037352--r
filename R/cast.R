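#' CAST sequences
#'
#' A CAST (Cell Alignment Search Tool) token writes one cell's
#' differentiation code as `D.letters`: `D` is the cell's depth and the
#' letters substitute `C` (contraction) for bit 0 and `E` (expansion) for
#' bit 1, e.g. bits `0,1,0` at depth 3 become `"3.CEC"`. A `cast_sequence`
#' is an ordered set of such tokens from one tree; the canonical order is
#' ascending depth, then the letter string read as a binary number.
#'
#' @param tokens character vector of `D.letters` tokens
#' @param source identifier of the originating tree/file
#' @param canonical sort tokens into canonical order?
#' @return object of class `cast_sequence` (a character vector with
#'   attributes `source` and `canonical`)
#' @export
cast_sequence <- function(tokens, source = NA_character_, canonical = TRUE) {
  tokens <- as.character(tokens)
  bad <- !grepl("^[0-9]+\\.[CE]+$", tokens)
  if (any(bad)) {
    stop("malformed CAST token(s): ", paste(tokens[bad], collapse = ", "))
  }
  d <- as.integer(sub("\\..*$", "", tokens))
  letters_ <- sub("^[0-9]+\\.", "", tokens)
  mism <- d != nchar(letters_)
  if (any(mism)) {
    stop("depth prefix does not match letter count: ",
         paste(tokens[mism], collapse = ", "))
  }
  if (canonical) tokens <- tokens[order(d, letters_)]
  structure(tokens, source = source, canonical = canonical,
            class = "cast_sequence")
}

#' @export
as.character.cast_sequence <- function(x, ...) {
  as.vector(unclass(x), mode = "character")
}

#' @export
print.cast_sequence <- function(x, ...) {
  cat("<cast_sequence> ", length(x), " tokens",
      if (isTRUE(attr(x, "canonical"))) " (canonical order)", sep = "")
  src <- attr(x, "source")
  if (!is.na(src)) cat(" from ", src, sep = "")
  cat("\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Encode a tree's differentiation codes as a CAST sequence
#'
#' One token per non-root cell (the root's code is empty). The tree must
#' already carry a differentiation or composite ordering; encode after
#' [order_differentiation()] (and any [apply_ordering_overrides()]).
#'
#' @param tree a `lineage_tree` with `ordering` `"differentiation"` or
#'   `"composite"`
#' @param max_depth keep only tokens with depth `<= max_depth` (e.g. 3 to
#'   compare only the first three rounds of division); `NULL` keeps all
#' @return a canonical [cast_sequence()]
#' @export
cast_encode <- function(tree, max_depth = NULL) {
  if (tree$ordering == "lineage") {
    stop("tree has no differentiation ordering; call order_differentiation() first")
  }
  codes <- assign_codes(tree, which = "active")
  codes <- codes[names(codes) != tree$root]
  letters_ <- chartr("01", "CE", unname(codes))
  tok <- paste0(nchar(letters_), ".", letters_)
  if (!is.null(max_depth)) tok <- tok[nchar(letters_) <= max_depth]
  cast_sequence(tok, source = "tree", canonical = TRUE)
}

#' Read a CAST code file
#'
#' Plain text: one or more `D.LETTERS` tokens per line, separated by
#' whitespace or commas; `#` starts a comment. The file's own token order
#' can be preserved (to reproduce scores computed under a specific
#' serialization) or canonicalized.
#'
#' @param path file path
#' @param order `"canonical"` (default) or `"file"`
#' @param source label recorded on the sequence (default: the file name)
#' @return a [cast_sequence()]
#' @export
cast_parse <- function(path, order = c("canonical", "file"), source = NULL) {
  order <- match.arg(order)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tok <- unlist(strsplit(lines, "[,[:space:]]+"))
  tok <- tok[nzchar(tok)]
  if (!length(tok)) stop("no CAST tokens in ", path)
  cast_sequence(tok, source = if (is.null(source)) basename(path) else source,
                canonical = order == "canonical")
}

#' Write a CAST sequence to a file
#'
#' @param x a [cast_sequence()]
#' @param path output path (one token per line)
#' @return `path`, invisibly
#' @export
cast_write <- function(x, path) {
  writeLines(unclass(x), path)
  invisible(path)
}

#' Globally align two CAST sequences
#'
#' Needleman-Wunsch over whole tokens: a token can only be paired with an
#' identical token (same depth and letters); there is no substitution state
#' by default. Scoring adds `match` for each pair and `gap` for each
#' position where only one sequence contributes. Traceback ties are broken
#' deterministically (match, then gap in `a`, then gap in `b`); the score is
#' tie-invariant.
#'
#' @param a,b [cast_sequence()] objects (or token vectors); canonicalized
#'   first unless already flagged canonical
#' @param match score for an identical token pair (default +1)
#' @param gap score for an unpaired token (default -1)
#' @param substitution score for pairing two different tokens, or `NULL`
#'   (default) to disallow substitutions entirely
#' @param canonicalize sort both sequences into canonical order before
#'   aligning (default). Set `FALSE` to align in the sequences' own stored
#'   order, e.g. to reproduce scores computed under a file's native
#'   serialization.
#' @return object of class `cast_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length token vectors with `"-"` for gaps), `length`, `score`,
#'   `matches`, `gaps`
#' @export
cast_align <- function(a, b, match = 1, gap = -1, substitution = NULL,
                       canonicalize = TRUE) {
  a <- as_cast_tokens(a, canonicalize)
  b <- as_cast_tokens(b, canonicalize)
  n <- length(a); m <- length(b)
  sub_pen <- if (is.null(substitution)) -Inf else substitution
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    ai <- a[i]
    for (j in seq_len(m)) {
      diag_sc <- S[i, j] + if (ai == b[j]) match else sub_pen
      S[i + 1, j + 1] <- max(diag_sc, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  # traceback, preferring match/substitution, then gap in a, then gap in b
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    cur <- S[i + 1, j + 1]
    if (i > 0 && j > 0 &&
        cur == S[i, j] + (if (a[i] == b[j]) match else sub_pen)) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1; j <- j - 1
    } else if (j > 0 && cur == S[i + 1, j] + gap) {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1
    } else {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1
    }
  }
  matches <- sum(ra == rb)
  gaps <- sum(ra == "-") + sum(rb == "-")
  structure(list(aligned_a = ra, aligned_b = rb, length = length(ra),
                 score = S[n + 1, m + 1], matches = matches, gaps = gaps),
            class = "cast_alignment")
}

as_cast_tokens <- function(x, canonicalize = TRUE) {
  tok <- if (inherits(x, "cast_sequence")) unclass(x) else as.character(x)
  keep_order <- !canonicalize ||
    (inherits(x, "cast_sequence") && isTRUE(attr(x, "canonical")))
  unclass(cast_sequence(tok, canonical = !keep_order))
}

#' @export
print.cast_alignment <- function(x, ...) {
  cat(cast_align_report(x), sep = "\n")
  invisible(x)
}

#' Text report for a CAST alignment
#'
#' Reports alignment length, score, the score as a percentage of the length
#' (rounded to the nearest integer percent), and the matched and unmatched
#' token lists.
#'
#' @param result a `cast_alignment`
#' @return character vector of report lines
#' @export
cast_align_report <- function(result) {
  stopifnot(inherits(result, "cast_alignment"))
  pct <- round(100 * result$score / result$length)
  matched <- result$aligned_a[result$aligned_a == result$aligned_b]
  only_a <- result$aligned_a[result$aligned_b == "-"]
  only_b <- result$aligned_b[result$aligned_a == "-"]
  c(sprintf("CAST alignment: length %d, score %d (%d%% of the length)",
            result$length, result$score, pct),
    sprintf("matches: %d; gaps: %d", result$matches, result$gaps),
    paste0("matched tokens: ",
           if (length(matched)) paste(matched, collapse = " ") else "(none)"),
    paste0("only in a: ",
           if (length(only_a)) paste(only_a, collapse = " ") else "(none)"),
    paste0("only in b: ",
           if (length(only_b)) paste(only_b, collapse = " ") else "(none)"))
}

#' Write the aligned token pairs as CSV
#'
#' @param result a `cast_alignment`
#' @param path output path; columns `token_a,token_b` with `-` for gaps
#' @return `path`, invisibly
#' @export
cast_alignment_csv <- function(result, path) {
  utils::write.csv(data.frame(token_a = result$aligned_a,
                              token_b = result$aligned_b),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
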