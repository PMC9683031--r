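# Gazetteer (lexicon) lookup: the first stage of the cascade.  Entries are
# matched longest-first on token boundaries; matching is shared with the
# ConText trigger scanner.

#' Read one gazetteer lexicon file
#'
#' UTF-8, one entry per line, tab-separated:
#' `term<TAB>majorType<TAB>minorType<TAB>conceptCode`; trailing fields may be
#' omitted; lines starting with `#` are comments.
#'
#' @param path Lexicon file path.
#' @param name Lexicon name (defaults to the file stem).
#' @return A tibble with columns `term`, `majorType`, `minorType`,
#'   `conceptCode`, `caseSensitive`, `gazetteer`.
#' @export
read_gazetteer <- function(path, name = sub("\\.lst$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(i) {
    map_chr(fields, function(f) {
      v <- if (length(f) >= i) trimws(f[[i]]) else ""
      if (nzchar(v)) v else NA_character_
    })
  }
  tibble(
    term = grab(1), majorType = grab(2), minorType = grab(3),
    conceptCode = grab(4), caseSensitive = FALSE, gazetteer = name
  )
}

#' Read a gazetteer index file
#'
#' The index (`.def`) file lists one member lexicon (`.lst`) file per line,
#' relative to the index file's directory; `#` comments allowed.
#'
#' @param path Index file path.
#' @return All member entries, row-bound (see [read_gazetteer()]).
#' @export
read_gazetteer_index <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)])
  dir <- dirname(path)
  list_rbind(lapply(lines, function(f) read_gazetteer(file.path(dir, f))))
}

# Tokenize a term and record inter-token gaps (must be "" or " " in a match).
term_parts <- function(term) {
  toks <- tokenize(term)
  if (nrow(toks) == 0) return(NULL)
  txt <- covered_text(toks, term)
  gaps <- if (nrow(toks) > 1) {
    substring(term, toks$end[-nrow(toks)] + 1L, toks$start[-1])
  } else {
    character()
  }
  list(tokens = txt, gaps = gaps)
}

#' Compile gazetteer entries into a lookup index
#'
#' Builds an index supporting longest-match scanning over tokenised text.
#' Case-insensitive entries are case-folded; multi-word terms match across
#' single spaces; matches start and end on token boundaries.  Duplicate
#' `(term, majorType, minorType)` triples (after case folding of
#' case-insensitive terms) are a validation error listing the offenders.
#'
#' @param entries Entry tibble, as returned by [read_gazetteer()] /
#'   [read_gazetteer_index()], possibly row-bound across lexicons.
#' @return An object of class `bcc_lookup_index`.
#' @export
compile_gazetteer <- function(entries) {
  stopifnot(is.data.frame(entries))
  entries <- as_tibble(entries)
  if (!"caseSensitive" %in% names(entries)) entries$caseSensitive <- FALSE
  if (!"minorType" %in% names(entries)) entries$minorType <- NA_character_
  if (!"conceptCode" %in% names(entries)) entries$conceptCode <- NA_character_
  entries$term <- trimws(gsub("[[:space:]]+", " ", entries$term))
  entries <- entries[nzchar(entries$term), , drop = FALSE]
  if (nrow(entries) == 0) abort("cannot compile an empty gazetteer collection")
  folded <- ifelse(entries$caseSensitive, entries$term, tolower(entries$term))
  key <- paste(folded, entries$majorType, entries$minorType, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- entries$term[duplicated(key) | duplicated(key, fromLast = TRUE)]
    abort(paste0(
      "duplicate gazetteer entries (after case folding): ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  parts <- lapply(entries$term, term_parts)
  ok <- !vapply(parts, is.null, logical(1))
  entries <- entries[ok, , drop = FALSE]
  parts <- parts[ok]
  n_tok <- vapply(parts, function(p) length(p$tokens), integer(1))
  first_tok <- vapply(parts, function(p) p$tokens[[1]], character(1))
  first_key <- ifelse(entries$caseSensitive, first_tok, tolower(first_tok))
  tab <- tibble(
    row = seq_len(nrow(entries)),
    first = first_key,
    n_tok = n_tok,
    parts = parts,
    caseSensitive = entries$caseSensitive
  )
  by_first <- split(tab[order(-tab$n_tok), ], tab$first[order(-tab$n_tok)])
  structure(
    list(entries = entries, by_first = by_first),
    class = "bcc_lookup_index"
  )
}

#' @export
print.bcc_lookup_index <- function(x, ...) {
  cat(
    "<bcc_lookup_index> ", nrow(x$entries), " entries, ",
    length(unique(x$entries$gazetteer)), " lexicons\n", sep = ""
  )
  invisible(x)
}

# Core scanner: longest match per start token.  Returns tibble
# (start, end, entry_row).  Shared by gazetteer lookup and trigger matching.
scan_index <- function(text, tokens, index) {
  out_start <- integer()
  out_end <- integer()
  out_row <- integer()
  ntok <- nrow(tokens)
  if (ntok == 0) return(tibble(start = integer(), end = integer(), entry_row = integer()))
  tok_txt <- covered_text(tokens, text)
  tok_fold <- tolower(tok_txt)
  for (i in seq_len(ntok)) {
    cands <- rbind(
      index$by_first[[tok_fold[i]]],
      if (tok_fold[i] != tok_txt[i]) index$by_first[[tok_txt[i]]]
    )
    if (is.null(cands) || nrow(cands) == 0) next
    cands <- cands[order(-cands$n_tok), , drop = FALSE]
    for (k in seq_len(nrow(cands))) {
      L <- cands$n_tok[k]
      if (i + L - 1L > ntok) next
      p <- cands$parts[[k]]
      doc_toks <- if (cands$caseSensitive[k]) {
        tok_txt[i:(i + L - 1L)]
      } else {
        tok_fold[i:(i + L - 1L)]
      }
      ref_toks <- if (cands$caseSensitive[k]) p$tokens else tolower(p$tokens)
      if (!identical(unname(doc_toks), unname(ref_toks))) next
      if (L > 1) {
        gaps <- substring(
          text,
          tokens$end[i:(i + L - 2L)] + 1L,
          tokens$start[(i + 1L):(i + L - 1L)]
        )
        if (!identical(unname(gaps), unname(p$gaps))) next
      }
      out_start <- c(out_start, tokens$start[i])
      out_end <- c(out_end, tokens$end[i + L - 1L])
      out_row <- c(out_row, cands$row[k])
      break # longest match only at this start offset
    }
  }
  tibble(start = out_start, end = out_end, entry_row = out_row)
}

#' Run gazetteer lookup over a document
#'
#' Produces `Lookup` annotations carrying `majorType`, `minorType` and
#' `conceptCode` features.  Matches start and end on token boundaries; at
#' each start offset only the longest match is emitted; overlapping matches
#' with different start offsets are all kept.  Output is invariant to the
#' order in which lexicon files were read.
#'
#' @param text Document text.
#' @param tokens Token annotation table from [tokenize()].
#' @param index Compiled index from [compile_gazetteer()].
#' @return An annotation table of category `"Lookup"`.
#' @export
gaz_lookup <- function(text, tokens, index) {
  stopifnot(inherits(index, "bcc_lookup_index"))
  hits <- scan_index(text, tokens, index)
  if (nrow(hits) == 0) return(annotation_tbl())
  ent <- index$entries[hits$entry_row, , drop = FALSE]
  feats <- pmap(
    list(ent$majorType, ent$minorType, ent$conceptCode),
    function(mj, mn, cc) {
      f <- list(majorType = mj)
      if (!is.na(mn)) f$minorType <- mn
      if (!is.na(cc)) f$conceptCode <- cc
      f
    }
  )
  annotation_tbl(
    category = rep("Lookup", nrow(hits)),
    start = hits$start, end = hits$end, features = feats
  )
}
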