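#' SMILES token vocabulary
#'
#' Fixed symbol table for the longest-match SMILES tokenizer. Multi-character
#' atom symbols (`Cl`, `Br`), bracket atoms (e.g. `[nH]`, `[N+]`) and
#' two-digit ring closures (`%10` ...) are single tokens. The first three
#' entries are the sentinels `<pad>`, `<bos>`, `<eos>`.
#'
#' @return Character vector of token symbols; the integer position of a
#'   symbol is its vocabulary index.
#' @export
smilesVocabulary <- function() {
  c("<pad>", "<bos>", "<eos>",
    "Cl", "Br",
    "B", "C", "N", "O", "P", "S", "F", "I",
    "b", "c", "n", "o", "p", "s",
    "[nH]", "[N+]", "[N-]", "[O-]", "[NH+]", "[NH2+]", "[NH3+]",
    "[C@H]", "[C@@H]", "[S+]", "[n+]", "[NH]", "[OH]",
    "(", ")", "=", "#", "-", "/", "\\", ":", ".", "@", "+",
    as.character(0:9), paste0("%", 10:29))
}

.tok_specials <- c("<pad>", "<bos>", "<eos>")

# Longest-match scan of one SMILES string into token symbols.
scan_smiles <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom starting at position ", i,
                      " in SMILES '", s, "'", call. = FALSE)
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" && i + 2L <= n) {
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Tokenize a SMILES string
#'
#' Deterministic longest-match tokenization over the fixed symbol table, with
#' begin/end sentinels. Truncation is never performed: a string that would
#' exceed `maxLen` is an error, as is any symbol absent from the vocabulary.
#'
#' @param s A single SMILES string.
#' @param vocab Token table, as from [smilesVocabulary()].
#' @param maxLen Maximum token count including sentinels.
#' @return Integer vector of vocabulary indices (class `TokenSequence`), with
#'   the matched symbols in `attr(, "symbols")`.
#' @examples
#' tokenizeSmiles("CCO")
#' @export
tokenizeSmiles <- function(s, vocab = smilesVocabulary(), maxLen = 128L) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) stop("empty SMILES string", call. = FALSE)
  syms <- scan_smiles(s)
  bad <- which(!(syms %in% vocab))
  if (length(bad) > 0L) {
    stop("unknown symbol '", syms[bad[1L]], "' (token ", bad[1L],
         ") in SMILES '", s, "'", call. = FALSE)
  }
  syms <- c("<bos>", syms, "<eos>")
  if (length(syms) > maxLen) {
    stop("SMILES '", s, "' tokenizes to ", length(syms),
         " tokens, exceeding maxLen = ", maxLen,
         "; truncation is not permitted", call. = FALSE)
  }
  idx <- match(syms, vocab)
  attr(idx, "symbols") <- syms
  class(idx) <- "TokenSequence"
  idx
}

#' Reassemble a SMILES string from a token sequence
#'
#' Inverse of [tokenizeSmiles()] up to the sentinel/padding tokens, which are
#' dropped.
#'
#' @param tokens Integer vector of vocabulary indices.
#' @param vocab Token table used to produce `tokens`.
#' @return The SMILES string.
#' @export
detokenizeSmiles <- function(tokens, vocab = smilesVocabulary()) {
  syms <- vocab[as.integer(tokens)]
  paste(syms[!(syms %in% .tok_specials)], collapse = "")
}

#' Canonicalize SMILES strings
#'
#' Maps every spelling of a molecule to one canonical SMILES (via OpenBabel).
#' Unparseable strings are an error naming the offending input: datasets with
#' invalid rows are rejected outright rather than silently shortened.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length and order.
#' @examples
#' canonicalSmiles(c("CCO", "OCC"))
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(!nzchar(smiles))) stop("empty SMILES string", call. = FALSE)
  out <- ob_canonical(smiles)
  if (length(out) == length(smiles) && !anyNA(out)) return(out)
  # batch conversion dropped rows: redo one-by-one to name the offender
  for (s in smiles) {
    one <- ob_canonical(s)
    if (length(one) != 1L || is.na(one) || !nzchar(one)) {
      stop("SMILES '", s, "' could not be parsed", call. = FALSE)
    }
  }
  stop("SMILES canonicalization failed", call. = FALSE)
}

ob_canonical <- function(smiles) {
  raw <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste(smiles, collapse = "\n")))
  if (!nzchar(raw)) return(character(0))
  out <- strsplit(raw, "\n", fixed = TRUE)[[1L]]
  out <- sub("\t.*$", "", out)
  out <- sub("\\s+$", "", out)
  out[nzchar(out)]
}

count_heavy_atoms <- function(canonical) {
  syms <- scan_smiles(canonical)
  atom <- grepl("^\\[", syms) |
    syms %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
                "b", "c", "n", "o", "p", "s")
  sum(atom)
}

.fp_cache <- new.env(parent = emptyenv())

#' Hashed atom-pair fingerprint
#'
#' Computes the atom-pair descriptor set of a molecule (every pair of heavy
#' atoms with its topological distance, via ChemmineR) and folds the integer
#' descriptor codes modulo `nBits` into a fixed-length presence/absence bit
#' vector. Because descriptors are computed on the molecular graph, every
#' SMILES spelling of the same molecule yields an identical fingerprint. A
#' molecule with fewer than two heavy atoms has no atom pairs and maps to the
#' all-zero vector.
#'
#' @param smiles A single SMILES string.
#' @param nBits Fingerprint length (default 2048).
#' @return Integer 0/1 vector of length `nBits`.
#' @examples
#' sum(atomPairFingerprint("C"))    # methane: no pairs
#' @export
atomPairFingerprint <- function(smiles, nBits = 2048L) {
  stopifnot(length(smiles) == 1L, nBits >= 1L)
  can <- canonicalSmiles(smiles)
  key <- paste0(can, "#", nBits)
  hit <- .fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  fp <- integer(nBits)
  if (count_heavy_atoms(can) >= 2L) {
    codes <- atom_pair_codes(can)
    fp[unique(codes %% as.integer(nBits)) + 1L] <- 1L
  }
  .fp_cache[[key]] <- fp
  fp
}

atom_pair_codes <- function(canonical) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canonical))
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  codes <- ChemmineR::ap(ap[1])[[1L]]
  if (length(codes) == 1L && codes[1L] == 1) {
    stop("atom-pair descriptors failed for SMILES '", canonical, "'",
         call. = FALSE)
  }
  codes
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles Character vector of SMILES strings.
#' @param nBits Fingerprint length.
#' @return Integer matrix, one row per input molecule, `nBits` columns; row
#'   names are the input strings.
#' @export
fingerprintMatrix <- function(smiles, nBits = 2048L) {
  m <- t(vapply(smiles, atomPairFingerprint, integer(nBits), nBits = nBits))
  rownames(m) <- smiles
  m
}

#' Tanimoto similarity of two bit vectors
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Intersection over union of the set bits; 0 when both are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}
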