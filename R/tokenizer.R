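# SMILES tokenisation and vocabularies.
#
# Atom-level tokenisation: bracket atoms ([...]) are single tokens, the
# two-letter halogens Cl/Br are single tokens, ring-closure digits (and %nn
# two-digit closures), bond/stereo/branch symbols are single-character tokens.

.smiles_token_re <- paste0(
  "\\[[^\\]]*\\]", "|",   # bracket atom
  "Br|Cl", "|",           # two-letter elements
  "%[0-9]{2}", "|",       # two-digit ring closure
  "[A-Za-z]", "|",        # one-letter atoms (incl. aromatic lowercase)
  "[0-9]", "|",           # ring-bond digits
  "[()=#+/\\\\.:@~*$-]"   # bonds, branches, stereo, charge symbols
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atom-level tokens: bracket atoms such as
#' `[O-]` or `[nH]` become one token, `Cl`/`Br` are kept whole, and every
#' ring digit, bond or branch symbol is a single token. Characters outside
#' the pattern are kept as single-character tokens (they map to the UNK id
#' under a vocabulary).
#'
#' @param smiles nonempty character scalar.
#' @param vocab optional named integer vocabulary (see [build_vocab()]); when
#'   given, integer token ids are returned instead of token strings, with
#'   unknown tokens mapped to the UNK id.
#' @param max_len optional length: id sequences are truncated or padded with
#'   the PAD id (0) to this length. Ignored unless `vocab` is given.
#' @return character vector of tokens, or integer id vector when `vocab` is
#'   supplied.
#' @examples
#' tokenize_smiles("c1ccccc1Cl")
#' tokenize_smiles("CC(=O)[O-]")
#' @export
tokenize_smiles <- function(smiles, vocab = NULL, max_len = NULL) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stop("smiles must be a nonempty string")
  }
  .check_brackets(smiles)
  m <- gregexpr(.smiles_token_re, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, gregexpr(.smiles_token_re, smiles, perl = TRUE))[[1]]
  # characters not consumed by the pattern become single-char (UNK) tokens
  covered <- rep(FALSE, nchar(smiles))
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
    }
  }
  if (!all(covered)) {
    pieces <- character(0)
    pos <- 1L
    k <- 1L
    while (pos <= nchar(smiles)) {
      if (m[1] != -1 && k <= length(m) && pos == m[k]) {
        len <- attr(m, "match.length")[k]
        pieces <- c(pieces, substr(smiles, pos, pos + len - 1))
        pos <- pos + len
        k <- k + 1L
      } else {
        pieces <- c(pieces, substr(smiles, pos, pos))
        pos <- pos + 1L
      }
    }
    toks <- pieces
  }
  if (is.null(vocab)) return(toks)
  ids <- unname(vocab[toks])
  ids[is.na(ids)] <- vocab[[".UNK"]]
  if (!is.null(max_len)) {
    ids <- ids[seq_len(min(length(ids), max_len))]
    if (length(ids) < max_len) ids <- c(ids, rep(vocab[[".PAD"]], max_len - length(ids)))
  }
  as.integer(ids)
}

.check_brackets <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  open_at <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "[") {
      if (depth > 0) stop(sprintf("nested '[' at position %d in %s", i, smiles))
      depth <- 1L
      open_at <- i
    } else if (chars[i] == "]") {
      if (depth == 0) stop(sprintf("unbalanced ']' at position %d in %s", i, smiles))
      depth <- 0L
    }
  }
  if (depth > 0) stop(sprintf("unbalanced '[' at position %d in %s", open_at, smiles))
  invisible(TRUE)
}

#' Build a token vocabulary from SMILES strings
#'
#' Reserved ids: PAD = 0 (stored under `.PAD`) and UNK = 1 (under `.UNK`);
#' observed tokens get consecutive ids from 2 in sorted order.
#'
#' @param smiles_list character vector of SMILES strings.
#' @return named integer vector mapping token to id.
#' @export
build_vocab <- function(smiles_list) {
  toks <- sort(unique(unlist(lapply(smiles_list, tokenize_smiles))))
  ids <- c(0L, 1L, seq_along(toks) + 1L)
  names(ids) <- c(".PAD", ".UNK", toks)
  ids
}

#' Assemble a drug library
#'
#' Maps drug ids to SMILES strings and integer token sequences under a shared
#' vocabulary with reserved PAD (0) and UNK (1) ids.
#'
#' @param drug_ids character vector of unique drug identifiers.
#' @param smiles character vector of SMILES strings, same length.
#' @param vocab optional vocabulary; built from `smiles` when `NULL`.
#' @param max_len optional fixed sequence length (truncate/pad).
#' @return object of class `mkdr_druglib`: list with `drug_ids`, `smiles`,
#'   `token_seqs`, `vocab`, `max_len`.
#' @export
drug_library <- function(drug_ids, smiles, vocab = NULL, max_len = NULL) {
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids")
  if (length(drug_ids) != length(smiles)) stop("drug_ids and smiles lengths differ")
  if (is.null(vocab)) vocab <- build_vocab(smiles)
  seqs <- lapply(smiles, tokenize_smiles, vocab = vocab, max_len = max_len)
  names(seqs) <- drug_ids
  names(smiles) <- drug_ids
  stopifnot(all(unlist(seqs) < length(vocab)))
  structure(list(drug_ids = drug_ids, smiles = smiles, token_seqs = seqs,
                 vocab = vocab, max_len = max_len),
            class = "mkdr_druglib")
}

#' @export
print.mkdr_druglib <- function(x, ...) {
  cat(sprintf("Drug library: %d drugs, vocabulary of %d tokens (PAD=0, UNK=1)\n",
              length(x$drug_ids), length(x$vocab)))
  invisible(x)
}

# token sequences as a padded integer matrix (n_drugs x L), PAD = 0
.token_matrix <- function(drugs, max_len = NULL) {
  lens <- vapply(drugs$token_seqs, function(s) sum(s != 0L), 1L)
  L <- if (is.null(max_len)) max(vapply(drugs$token_seqs, length, 1L)) else max_len
  out <- matrix(0L, length(drugs$token_seqs), L)
  for (i in seq_along(drugs$token_seqs)) {
    s <- drugs$token_seqs[[i]]
    s <- s[seq_len(min(length(s), L))]
    out[i, seq_along(s)] <- s
  }
  rownames(out) <- drugs$drug_ids
  out
}
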