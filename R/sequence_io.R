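#' Read a temporal edge list
#'
#' Parses plain-text contact lists in the `t u v` convention used by wearable
#' proximity studies: one record per line, whitespace- or tab-separated, first
#' three fields the integer timestamp and the two node ids.  Extra columns are
#' ignored and lines starting with `#` are comments.  Records are sorted
#' stably by timestamp (ties keep their file order), so that the flattened
#' sequence of edges is reproducible.
#'
#' @param source path to a file, or a character vector of lines (useful for
#'   tests and inline examples).
#' @param drop_self_loops if `TRUE`, records with `u == v` are dropped with a
#'   warning; otherwise they are an error.
#' @return an object of class `temporal_edges`: a `data.frame` with integer
#'   columns `t`, `u`, `v`, carrying the number of distinct nodes in
#'   `attr(, "N")`.
#' @seealso [tokenize()] to convert to a token sequence.
#' @export
read_temporal_edges <- function(source, drop_self_loops = FALSE) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source, warn = FALSE)
  else
    unlist(strsplit(as.character(source), "\n", fixed = TRUE), use.names = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(temporal_edges(integer(0), integer(0), integer(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 whitespace-separated fields")
  t <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  u <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  v <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- !is.finite(t)
  if (any(bad))
    stop("malformed line ", lineno[which(bad)[1L]], ": non-integer timestamp")
  bad <- !is.finite(u) | !is.finite(v)
  if (any(bad))
    stop("malformed line ", lineno[which(bad)[1L]], ": non-integer node id")
  loop <- u == v
  if (any(loop)) {
    if (!drop_self_loops)
      stop("self-loop (u == v) on line ", lineno[which(loop)[1L]],
           "; use drop_self_loops = TRUE to discard such records")
    warning("dropped ", sum(loop), " self-loop record(s)")
    t <- t[!loop]; u <- u[!loop]; v <- v[!loop]
  }
  temporal_edges(t, u, v)
}

#' Construct a temporal edge list from vectors
#'
#' @param t,u,v integer vectors of equal length: timestamps and node ids.
#' @return a `temporal_edges` data frame, stably sorted by `t`.
#' @export
temporal_edges <- function(t, u, v) {
  t <- as.integer(t); u <- as.integer(u); v <- as.integer(v)
  stopifnot(length(u) == length(t), length(v) == length(t))
  if (any(u == v)) stop("self-loops (u == v) are not allowed")
  o <- order(t, method = "radix")  # radix sort is stable
  out <- data.frame(t = t[o], u = u[o], v = v[o])
  attr(out, "N") <- length(unique(c(u, v)))
  class(out) <- c("temporal_edges", "data.frame")
  out
}

#' @export
print.temporal_edges <- function(x, ...) {
  cat("Temporal edge list: ", nrow(x), " record(s), N = ",
      attr(x, "N"), " node(s)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... (", nrow(x) - 10L, " more)\n", sep = "")
  invisible(x)
}

#' Write a temporal edge list to a plain-text file
#'
#' @param edges a `temporal_edges` object.
#' @param path output file path.
#' @export
write_temporal_edges <- function(edges, path) {
  writeLines(paste(edges$t, edges$u, edges$v), path)
  invisible(path)
}

#' Tokenize a temporal edge list
#'
#' Canonicalizes each undirected edge as the pair `(min(u,v), max(u,v))` and
#' maps distinct pairs to integer tokens `0..D-1` in order of first
#' appearance.  Records sharing a timestamp are serialized in their stable
#' file order, so model time is simply the 1-based index into the flattened
#' sequence.
#'
#' @param edges a `temporal_edges` object (non-empty).
#' @return a [token_sequence()] with alphabet mapping tokens back to node
#'   pairs.
#' @export
tokenize <- function(edges) {
  stopifnot(inherits(edges, "temporal_edges"))
  if (nrow(edges) == 0L) stop("empty edge list")
  pu <- pmin(edges$u, edges$v)
  pv <- pmax(edges$u, edges$v)
  key <- paste(pu, pv)
  first <- !duplicated(key)
  tokens <- match(key, key[first]) - 1L
  alphabet <- cbind(u = pu[first], v = pv[first])
  token_sequence(tokens, D = sum(first), alphabet = alphabet,
                 N = attr(edges, "N"))
}

#' Token sequence
#'
#' The core data object: an ordered sequence of integer tokens
#' `0..D-1`, each token standing for one undirected edge of the network.
#' `tokenize()` always produces a sequence in which every token value occurs;
#' the constructor also accepts an explicit `D` larger than the observed
#' support (useful for sequences drawn from a known generative model where a
#' rare token may never be emitted).  When `D` is omitted, tokens are
#' relabelled densely by first appearance.
#'
#' @param tokens integer vector of tokens (0-based).
#' @param D alphabet size; defaults to the number of distinct tokens (with
#'   dense relabelling).
#' @param alphabet optional `D x 2` integer matrix mapping token `i` (row
#'   `i + 1`) to its canonical node pair; defaults to a synthetic pair
#'   assignment over the smallest complete graph with at least `D` edges.
#' @param N number of nodes; defaults to the nodes present in `alphabet`.
#' @return an object of class `token_sequence` with fields `tokens`, `E`,
#'   `D`, `alphabet`, `N`.
#' @export
token_sequence <- function(tokens, D = NULL, alphabet = NULL, N = NULL) {
  tokens <- as.integer(tokens)
  if (length(tokens) == 0L) stop("empty token sequence")
  if (any(tokens < 0L)) stop("tokens must be non-negative integers")
  if (is.null(D)) {
    first <- !duplicated(tokens)
    tokens <- match(tokens, tokens[first]) - 1L
    D <- sum(first)
  } else {
    D <- as.integer(D)
    if (max(tokens) >= D) stop("token value >= D")
  }
  if (is.null(alphabet)) alphabet <- synthetic_alphabet(D)
  alphabet <- cbind(u = as.integer(alphabet[, 1L]), v = as.integer(alphabet[, 2L]))
  if (nrow(alphabet) != D) stop("alphabet must have one row per token")
  if (anyDuplicated(paste(pmin(alphabet[, 1], alphabet[, 2]),
                          pmax(alphabet[, 1], alphabet[, 2]))))
    stop("alphabet maps two tokens to the same node pair")
  structure(list(tokens = tokens, E = length(tokens), D = D,
                 alphabet = alphabet,
                 N = N %||% length(unique(c(alphabet[, 1L], alphabet[, 2L])))),
            class = "token_sequence")
}

#' Canonical synthetic alphabet
#'
#' Assigns tokens `0..D-1` to the lexicographically first `D` edges of the
#' smallest complete graph with at least `D` edges.  Used for sequences that
#' do not originate from an observed contact list (planted models, examples).
#'
#' @param D alphabet size.
#' @return a `D x 2` integer matrix of node pairs (nodes numbered from 1).
#' @export
synthetic_alphabet <- function(D) {
  N <- 2L
  while (N * (N - 1L) / 2L < D) N <- N + 1L
  pairs <- t(utils::combn(N, 2L))
  pairs <- pairs[seq_len(D), , drop = FALSE]
  cbind(u = pairs[, 1L], v = pairs[, 2L])
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("Token sequence: E = ", x$E, ", D = ", x$D, ", N = ", x$N, "\n", sep = "")
  cat("  tokens: ", paste(utils::head(x$tokens, 15L), collapse = " "),
      if (x$E > 15L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Expand a token sequence back into a temporal edge list
#'
#' Record `i` receives timestamp `i - 1` (the event clock) and the canonical
#' node pair of token `x_i`; `tokenize(detokenize(s))` reproduces `s` whenever
#' every token of `s` is observed.
#'
#' @param seq a `token_sequence`.
#' @return a `temporal_edges` data frame.
#' @export
detokenize <- function(seq) {
  stopifnot(inherits(seq, "token_sequence"))
  temporal_edges(t = seq_len(seq$E) - 1L,
                 u = seq$alphabet[seq$tokens + 1L, 1L],
                 v = seq$alphabet[seq$tokens + 1L, 2L])
}

#' Serialize / read a token sequence as JSON
#'
#' The JSON object stores `tokens`, `alphabet` (token id to `[u, v]`), `E`,
#' `D` and `N`.
#'
#' @param seq a `token_sequence`.
#' @param path file path.
#' @return `read_token_sequence_json` returns a `token_sequence`.
#' @export
write_token_sequence_json <- function(seq, path) {
  alpha <- stats::setNames(
    lapply(seq_len(seq$D), function(i) seq$alphabet[i, ]),
    as.character(seq_len(seq$D) - 1L))
  jsonlite::write_json(
    list(tokens = seq$tokens, alphabet = alpha,
         E = seq$E, D = seq$D, N = seq$N),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_token_sequence_json
#' @export
read_token_sequence_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- do.call(rbind, obj$alphabet[as.character(seq_len(obj$D) - 1L)])
  token_sequence(obj$tokens, D = obj$D, alphabet = alpha, N = obj$N)
}
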