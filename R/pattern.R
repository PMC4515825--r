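#' Parse a PROSITE-dialect sequence pattern
#'
#' Parses the motif dialect used for thiamin-binding patterns: exact
#' one-letter residues, residue classes in square brackets (`[ST]`),
#' exclusion classes in braces (`{P}`, normalized to the complementary
#' class), the wildcard `x`, and repeat counts `(n)` or `(n,m)` attached to
#' any element. Leading `<`, trailing `>`, a trailing period and `-`
#' separators are accepted and stripped.
#'
#' @param text Pattern string, e.g. `"[ILV][ST][ST][ST]N"`.
#' @param id Label stored with the pattern; defaults to the normalized text.
#' @param source_note Optional free-text provenance note (e.g. which
#'   structure the motif was derived from).
#'
#' @return A `prosite_pattern` object: an ordered element table
#'   (`kind`, `residues`, `min_repeat`, `max_repeat`) plus `id` and
#'   `source_note` attributes. `format()`/`print()` render the canonical
#'   text form (class residues alphabetized), and
#'   `parse_pattern(pattern_to_string(p))` is the identity.
#'
#' @examples
#' p <- parse_pattern("[QK]x(0,1)Dx(0,1)[TS]Dx(3)[ACMVITS][LVIMF]")
#' pattern_bounds(p)
#' @export
parse_pattern <- function(text, id = NULL, source_note = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    tt_abort("`text` must be a single pattern string.", "malformed_pattern")
  }
  raw <- gsub("\\s", "", text)
  raw <- sub("^<", "", raw)
  raw <- sub("\\.$", "", raw)
  raw <- sub(">$", "", raw)
  raw <- gsub("-", "", raw, fixed = TRUE)
  if (!nzchar(raw)) {
    tt_abort("Pattern is empty after normalization.", "malformed_pattern")
  }

  elements <- list()
  i <- 1L
  n <- nchar(raw)
  while (i <= n) {
    ch <- substr(raw, i, i)
    if (ch %in% c("[", "{")) {
      close <- if (ch == "[") "]" else "}"
      rest <- substr(raw, i + 1L, n)
      off <- regexpr(close, rest, fixed = TRUE)
      if (off < 0L) {
        tt_abort(
          paste0("Unbalanced '", ch, "' at position ", i, " of '", raw, "'."),
          "malformed_pattern"
        )
      }
      body <- substr(rest, 1L, off - 1L)
      listed <- unique(strsplit(toupper(body), "")[[1]])
      if (length(listed) == 0L) {
        tt_abort("Empty residue class in pattern.", "malformed_pattern")
      }
      if (!all(listed %in% AA20)) {
        tt_abort(
          paste0(
            "Non-amino-acid letter(s) in class: ",
            paste(setdiff(listed, AA20), collapse = ", ")
          ),
          "malformed_pattern"
        )
      }
      residues <- if (ch == "[") listed else setdiff(AA20, listed)
      if (length(residues) == 0L) {
        tt_abort("Exclusion class rules out every residue.", "malformed_pattern")
      }
      kind <- if (length(residues) >= 2L) "class" else "exact"
      i <- i + off + 1L
    } else if (ch %in% c("x", "X")) {
      kind <- "wildcard"
      residues <- character(0)
      i <- i + 1L
    } else if (toupper(ch) %in% AA20 && ch == toupper(ch)) {
      kind <- "exact"
      residues <- ch
      i <- i + 1L
    } else {
      tt_abort(
        paste0("Unexpected character '", ch, "' at position ", i, "."),
        "malformed_pattern"
      )
    }

    min_rep <- 1L
    max_rep <- 1L
    if (i <= n && substr(raw, i, i) == "(") {
      rest <- substr(raw, i + 1L, n)
      off <- regexpr(")", rest, fixed = TRUE)
      if (off < 0L) {
        tt_abort("Unbalanced '(' in repeat specification.", "malformed_pattern")
      }
      body <- substr(rest, 1L, off - 1L)
      if (grepl("^[0-9]+$", body)) {
        min_rep <- max_rep <- as.integer(body)
      } else if (grepl("^[0-9]+,[0-9]+$", body)) {
        parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
        min_rep <- parts[1]
        max_rep <- parts[2]
      } else {
        tt_abort(
          paste0("Malformed repeat '(", body, ")'."),
          "malformed_pattern"
        )
      }
      if (max_rep < min_rep) {
        tt_abort(
          paste0("Repeat maximum below minimum in '(", body, ")'."),
          "malformed_pattern"
        )
      }
      i <- i + off + 1L
    }
    if (kind != "wildcard" && max_rep < 1L) {
      tt_abort("Zero repeats are only meaningful for wildcards.", "malformed_pattern")
    }

    elements[[length(elements) + 1L]] <- list(
      kind = kind,
      residues = sort(residues),
      min_repeat = min_rep,
      max_repeat = max_rep
    )
  }

  el <- tibble::tibble(
    kind = vapply(elements, `[[`, character(1), "kind"),
    residues = lapply(elements, `[[`, "residues"),
    min_repeat = vapply(elements, `[[`, integer(1), "min_repeat"),
    max_repeat = vapply(elements, `[[`, integer(1), "max_repeat")
  )
  structure(
    list(
      id = id %||% pattern_text_from_elements(el),
      elements = el,
      source_note = source_note
    ),
    class = "prosite_pattern"
  )
}

pattern_text_from_elements <- function(el) {
  core <- vapply(seq_len(nrow(el)), function(i) {
    switch(el$kind[i],
      exact = el$residues[[i]],
      class = paste0("[", paste(el$residues[[i]], collapse = ""), "]"),
      wildcard = "x"
    )
  }, character(1))
  rep_sfx <- vapply(seq_len(nrow(el)), function(i) {
    mn <- el$min_repeat[i]
    mx <- el$max_repeat[i]
    if (mn == 1L && mx == 1L) "" else if (mn == mx) {
      paste0("(", mn, ")")
    } else {
      paste0("(", mn, ",", mx, ")")
    }
  }, character(1))
  paste0(core, rep_sfx, collapse = "")
}

#' Canonical text form of a pattern
#'
#' @param pattern A `prosite_pattern`.
#' @return A single string; re-parsing it reproduces the same element table.
#' @export
pattern_to_string <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  pattern_text_from_elements(pattern$elements)
}

#' @export
format.prosite_pattern <- function(x, ...) {
  paste0("<prosite_pattern ", x$id, "> ", pattern_to_string(x))
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Minimum and maximum match length of a pattern
#'
#' @param pattern A `prosite_pattern`.
#' @return A one-row tibble with `min_len` and `max_len` (element-wise sums
#'   of the repeat bounds).
#' @export
pattern_bounds <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  tibble::tibble(
    min_len = sum(pattern$elements$min_repeat),
    max_len = sum(pattern$elements$max_repeat)
  )
}

## Does element `el_row` accept the run chars[q..q+len-1]?
## 'X' in a sequence is accepted by wildcards only (conservative policy).
element_accepts <- function(chars, q, len, kind, residues) {
  if (len == 0L) {
    return(TRUE)
  }
  if (q + len - 1L > length(chars)) {
    return(FALSE)
  }
  run <- chars[q:(q + len - 1L)]
  if (kind == "wildcard") {
    return(TRUE)
  }
  all(run %in% residues)
}

## Set of end positions (inclusive) reachable from `start`, via a forward
## reachability sweep over elements; returns integer vector (may be empty).
match_ends_from <- function(chars, start, el) {
  n <- length(chars)
  reach <- start # positions = index of next unmatched residue
  for (i in seq_len(nrow(el))) {
    kind <- el$kind[i]
    residues <- el$residues[[i]]
    nxt <- integer(0)
    for (q in reach) {
      for (len in el$min_repeat[i]:el$max_repeat[i]) {
        if (q + len - 1L <= n && element_accepts(chars, q, len, kind, residues)) {
          nxt <- c(nxt, q + len)
        }
      }
    }
    reach <- unique(nxt)
    if (length(reach) == 0L) {
      return(integer(0))
    }
  }
  sort(reach - 1L)
}

## Leftmost-shortest element assignment for a fixed (start, end):
## depth-first over element lengths in increasing order, so earlier
## variable elements take the shortest length compatible with a full tiling.
assign_spans <- function(chars, start, end, el) {
  m <- nrow(el)
  lens <- integer(m)
  solve <- function(i, q) {
    if (i > m) {
      return(q == end + 1L)
    }
    for (len in el$min_repeat[i]:el$max_repeat[i]) {
      if (q + len - 1L <= end &&
        element_accepts(chars, q, len, el$kind[i], el$residues[[i]])) {
        lens[i] <<- len
        if (solve(i + 1L, q + len)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  if (!solve(1L, start)) {
    return(NULL)
  }
  starts <- start + c(0L, cumsum(lens)[-m])
  tibble::tibble(
    element = seq_len(m),
    start = starts,
    end = starts + lens - 1L # zero-length spans have end = start - 1
  )
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    tt_abort("`sequence` must be a single string.", "invalid_residue")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad) > 0L) {
    tt_abort(
      paste0(
        "Sequence contains non-amino-acid letter(s): ",
        paste(bad, collapse = ", ")
      ),
      "invalid_residue"
    )
  }
  chars
}

#' Scan one sequence for all matches of a pattern
#'
#' Reports every distinct `(start, end)` window admitting a valid element
#' assignment, including overlapping and nested matches (no greedy
#' suppression). Positions are 1-based inclusive. `X` in the sequence is
#' matched by wildcard elements only.
#'
#' @param pattern A `prosite_pattern`.
#' @param sequence A single amino-acid string (20-letter alphabet plus `X`).
#' @param sequence_id Identifier recorded in the result.
#' @return A tibble with columns `sequence_id`, `pattern_id`, `start`,
#'   `end`, `matched_text` and a list-column `element_spans` holding the
#'   leftmost-shortest per-element `(start, end)` tiling. Sorted by
#'   `start`, then `end`.
#' @examples
#' scan_sequence(parse_pattern("[ILV][ST][ST][ST]N"), "AISSTNA", "toy")
#' @export
scan_sequence <- function(pattern, sequence, sequence_id = "seq") {
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- validate_sequence(sequence)
  n <- length(chars)
  el <- pattern$elements

  hits <- list()
  if (n > 0L) {
    for (start in seq_len(n)) {
      ends <- match_ends_from(chars, start, el)
      ends <- ends[ends >= start] # drop degenerate zero-length windows
      for (end in ends) {
        hits[[length(hits) + 1L]] <- c(start, end)
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(
      sequence_id = character(0), pattern_id = character(0),
      start = integer(0), end = integer(0), matched_text = character(0),
      element_spans = list()
    ))
  }
  starts <- vapply(hits, `[`, integer(1), 1L)
  ends <- vapply(hits, `[`, integer(1), 2L)
  ord <- order(starts, ends)
  starts <- starts[ord]
  ends <- ends[ord]
  tibble::tibble(
    sequence_id = sequence_id,
    pattern_id = pattern$id,
    start = starts,
    end = ends,
    matched_text = vapply(
      seq_along(starts),
      function(k) paste(chars[starts[k]:ends[k]], collapse = ""),
      character(1)
    ),
    element_spans = lapply(
      seq_along(starts),
      function(k) assign_spans(chars, starts[k], ends[k], el)
    )
  )
}

#' Scan a FASTA collection for pattern matches
#'
#' @param pattern A `prosite_pattern`.
#' @param fasta Path to a FASTA file (wrapped or unwrapped), a
#'   [Biostrings::AAStringSet], or a named character vector of sequences.
#' @return The row-bound [scan_sequence()] tables in file order. Duplicate
#'   record ids trigger a warning; both records are still scanned.
#' @export
scan_collection <- function(pattern, fasta) {
  seqs <- read_fasta_sequences(fasta)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    rlang::warn(paste0(
      "Duplicate FASTA record id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      "; all records scanned."
    ))
  }
  out <- purrr::map2(seqs, ids, function(s, id) scan_sequence(pattern, s, id))
  dplyr::bind_rows(out)
}

read_fasta_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    set <- tryCatch(
      Biostrings::readAAStringSet(fasta),
      error = function(e) {
        tt_abort(
          paste0("Failed to parse FASTA file '", fasta, "': ", conditionMessage(e)),
          "fasta_parse"
        )
      }
    )
    seqs <- as.character(set)
    # FASTA headers: record id = first whitespace-delimited token
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  if (methods::is(fasta, "AAStringSet")) {
    seqs <- as.character(fasta)
    names(seqs) <- sub("\\s.*$", "", names(fasta))
    return(seqs)
  }
  if (is.character(fasta) && !is.null(names(fasta))) {
    return(fasta)
  }
  tt_abort(
    "`fasta` must be a file path, an AAStringSet, or a named character vector.",
    "fasta_parse"
  )
}

#' Write a match table as TSV
#'
#' Serializes the standard scan output columns (`sequence_id`,
#' `pattern_id`, `start`, `end`, `matched_text`); the `element_spans`
#' list-column is dropped.
#'
#' @param matches A tibble from [scan_sequence()]/[scan_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  keep <- intersect(
    c("sequence_id", "pattern_id", "start", "end", "matched_text"),
    names(matches)
  )
  readr::write_tsv(matches[keep], path)
  invisible(path)
}

#' The four thiamin-binding patterns
#'
#' The packaged pattern registry: `tpk` (derived from the human thiamin
#' diphosphokinase--ThDP complex), `tpk_thib` (hybrid thiamin
#' diphosphokinase / bacterial periplasmic thiamin-binding protein ThiB
#' serine-stretch motif), `thim` (bacterial
#' 4-methyl-5-(2-hydroxyethyl)-thiazole kinase ThiM, thiazole-binding), and
#' `thdp_motif` (the diphosphate/Mg-binding motif common to ThDP-dependent
#' enzymes).
#'
#' @param which Optional single registry name; when given, that
#'   `prosite_pattern` is returned directly.
#' @return A named list of `prosite_pattern` objects, or one pattern.
#' @examples
#' thiamin_patterns("tpk_thib")
#' @export
thiamin_patterns <- function(which = NULL) {
  registry <- list(
    tpk = c(
      "[QK]x(0,1)Dx(0,1)[TS]Dx(3)[ACMVITS][LVIMF]",
      "thiamin diphosphokinase, ThDP complex"
    ),
    tpk_thib = c(
      "[ILV][ST][ST][ST]N",
      "hybrid thiamin diphosphokinase / periplasmic ThiB serine stretch"
    ),
    thim = c(
      "Ax(9)[PA][AVILFM][MI]x(20,22)[GA][TSNKAH]",
      "thiazole kinase ThiM, thiazole-binding"
    ),
    thdp_motif = c(
      "G[DE][GA]x(24,30)NN",
      "ThDP-dependent enzyme diphosphate/Mg motif"
    )
  )
  pats <- lapply(names(registry), function(nm) {
    parse_pattern(registry[[nm]][1], id = nm, source_note = registry[[nm]][2])
  })
  names(pats) <- names(registry)
  if (!is.null(which)) {
    if (!which %in% names(pats)) {
      tt_abort(
        paste0(
          "Unknown pattern '", which, "'; available: ",
          paste(names(pats), collapse = ", ")
        ),
        "malformed_pattern"
      )
    }
    return(pats[[which]])
  }
  pats
}
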