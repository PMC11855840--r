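# Multi-level SMILES tokenization: functional-group substrings, bracketed
# ion groups, and single-character atom/bond tokens. Matching is purely
# textual on the SMILES string; the concatenation of tokens always
# reproduces the input exactly.

# Default functional-group patterns (high-frequency substrings; the aromatic
# benzene ring written canonically as c1ccccc1).
.FG_DEFAULTS <- c("C(=O)N", "OCC", "[N+](=O)[O-]", "c1ccccc1", "S(=O)",
                  "O=c", "NC(=O)", "NS(=O)(=O)", "OC", "S(=O)(=O)",
                  "C=O", "O=C")

# Candidate family for corpus mining: the defaults plus same-family motif
# variants (carbonyl / sulfonyl / ether / amide / ring attachments).
.FG_CANDIDATES <- unique(c(.FG_DEFAULTS,
  "C(=O)O", "C(=O)OC", "NC(=O)N", "S(=O)(=O)N", "C(=O)NC", "OCO", "COC",
  "CC(=O)", "c1ccncc1", "C(F)(F)F", "N=C", "C#N", "OCCO"))

#' Default functional-group vocabulary
#'
#' @return object of class `fg_vocab`: list with `patterns` (ordered by
#'   descending length, descending count, then lexicographically) and
#'   `counts`
#' @export
default_fg_vocab <- function() {
  .order_vocab(.FG_DEFAULTS, stats::setNames(rep(0L, length(.FG_DEFAULTS)), .FG_DEFAULTS))
}

.order_vocab <- function(patterns, counts) {
  patterns <- unique(patterns)
  cnt <- counts[patterns]
  cnt[is.na(cnt)] <- 0L
  ord <- order(-nchar(patterns), -cnt, patterns, method = "radix")
  structure(list(patterns = patterns[ord],
                 counts = stats::setNames(as.integer(cnt[ord]), patterns[ord])),
            class = "fg_vocab")
}

#' Mine high-frequency functional-group patterns from a SMILES corpus
#'
#' Counts substring occurrences of each candidate pattern (the default list
#' plus same-family variants) across the corpus. The returned vocabulary is
#' the union of the defaults and every candidate reaching `min_count`
#' occurrences, ordered by descending length, then descending count, then
#' lexicographically.
#'
#' @param smiles_corpus character vector of SMILES (may be empty)
#' @param min_count minimum occurrence count for non-default candidates
#' @return an `fg_vocab`
#' @export
mine_functional_groups <- function(smiles_corpus, min_count = 5L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  counts <- vapply(.FG_CANDIDATES, function(p) {
    if (length(smiles_corpus) == 0L) return(0L)
    sum(vapply(smiles_corpus, function(s)
      length(gregexpr(p, s, fixed = TRUE)[[1]][gregexpr(p, s, fixed = TRUE)[[1]] > 0]),
      integer(1)))
  }, integer(1))
  keep <- .FG_CANDIDATES %in% .FG_DEFAULTS | counts >= min_count
  .order_vocab(.FG_CANDIDATES[keep], counts[keep])
}

#' Tokenize a SMILES string into multi-level tokens
#'
#' Greedy left-to-right longest-match with three priorities: functional-group
#' patterns from the vocabulary, then bracketed groups `[...]` kept whole as
#' ion-group tokens, then single characters (two-letter organic-subset atoms
#' `Cl`/`Br` and `%NN` ring closures kept whole). Concatenating the tokens
#' reproduces the input string exactly.
#'
#' @param smiles SMILES string
#' @param fg_vocab an `fg_vocab` (or NULL for no functional-group matching)
#' @return object of class `token_sequence`: list with `tokens`, `levels`
#'   (factor levels "functional_group", "ion_group", "atom") and `length`
#' @examples
#' tokenize_smiles("CC(=O)N", default_fg_vocab())
#' @export
tokenize_smiles <- function(smiles, fg_vocab = default_fg_vocab()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  pats <- if (is.null(fg_vocab)) character(0) else fg_vocab$patterns
  plen <- nchar(pats)
  n <- nchar(smiles)
  tokens <- character(0); levels <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (k in seq_along(pats)) {
      j <- i + plen[k] - 1L
      if (j > n || substr(smiles, i, j) != pats[k]) next
      # a textual match must not cut a two-letter halogen: reject matches
      # ending in "C" before "l" or "B" before "r"
      last <- substr(smiles, j, j); nxt <- substr(smiles, j + 1L, j + 1L)
      if ((last == "C" && nxt == "l") || (last == "B" && nxt == "r")) next
      tokens <- c(tokens, pats[k]); levels <- c(levels, "functional_group")
      i <- i + plen[k]; matched <- TRUE; break
    }
    if (matched) next
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- i
      while (j <= n && substr(smiles, j, j) != "]") j <- j + 1L
      if (j > n) stop("unmatched '[' in SMILES: ", smiles)
      tokens <- c(tokens, substr(smiles, i, j)); levels <- c(levels, "ion_group")
      i <- j + 1L
    } else if (substr(smiles, i, i + 1L) %in% c("Cl", "Br")) {
      tokens <- c(tokens, substr(smiles, i, i + 1L)); levels <- c(levels, "atom")
      i <- i + 2L
    } else if (ch == "%" && i + 2L <= n) {
      tokens <- c(tokens, substr(smiles, i, i + 2L)); levels <- c(levels, "atom")
      i <- i + 3L
    } else {
      tokens <- c(tokens, ch); levels <- c(levels, "atom")
      i <- i + 1L
    }
  }
  structure(list(tokens = tokens, levels = levels, length = length(tokens),
                 smiles = smiles),
            class = "token_sequence")
}

#' Character-level SMILES tokenization
#'
#' The functional-group-splitting ablation baseline: every character is its
#' own atom-level token.
#'
#' @param smiles SMILES string
#' @return a `token_sequence`
#' @export
tokenize_chars <- function(smiles) {
  tk <- strsplit(smiles, "")[[1]]
  structure(list(tokens = tk, levels = rep("atom", length(tk)),
                 length = length(tk), smiles = smiles),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("token_sequence (%d tokens): %s\n", x$length,
              paste(sprintf("%s<%s>", x$tokens, substr(x$levels, 1, 2)), collapse = " ")))
  invisible(x)
}

#' Build a token dictionary from token sequences
#'
#' Indices are dense and 0-based: PAD = 0, UNK = 1, then all observed tokens
#' in sorted order.
#'
#' @param sequences list of `token_sequence`
#' @return object of class `token_dictionary`: list with `index` (named
#'   integer vector), `pad`, `unk`, `size`
#' @export
build_token_dictionary <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  toks <- sort(unique(unlist(lapply(sequences, `[[`, "tokens"))), method = "radix")
  idx <- stats::setNames(seq_along(toks) + 1L, toks)  # 2..|D|-1 (0-based: 2..)
  structure(list(index = idx, pad = 0L, unk = 1L, size = length(toks) + 2L),
            class = "token_dictionary")
}

#' Encode a token sequence as padded dictionary indices
#'
#' Truncates/pads to `max_len`. Returns 0-based indices (PAD = 0, UNK = 1), a
#' 0/1 mask, integer level tags (1 functional group, 2 ion group, 3 atom,
#' 0 pad), and optionally the one-hot matrix.
#'
#' @param seq a `token_sequence`
#' @param dict a `token_dictionary`
#' @param max_len maximum sequence length
#' @param onehot also return the `max_len` x `size` one-hot matrix
#' @return list with `indices`, `mask`, `levels`, and optionally `onehot`
#' @export
encode_sequence <- function(seq, dict, max_len = 128L, onehot = FALSE) {
  stopifnot(max_len >= 1L)
  tk <- utils::head(seq$tokens, max_len)
  lv <- utils::head(seq$levels, max_len)
  idx <- unname(dict$index[tk])
  idx[is.na(idx)] <- dict$unk
  mask <- c(rep(1L, length(idx)), rep(0L, max_len - length(idx)))
  lvl <- c(match(lv, c("functional_group", "ion_group", "atom")),
           rep(0L, max_len - length(idx)))
  idx <- c(idx, rep(dict$pad, max_len - length(idx)))
  out <- list(indices = idx, mask = mask, levels = lvl)
  if (onehot) {
    oh <- matrix(0, max_len, dict$size)
    real <- which(mask == 1L)
    oh[cbind(real, idx[real] + 1L)] <- 1
    out$onehot <- oh
  }
  out
}
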