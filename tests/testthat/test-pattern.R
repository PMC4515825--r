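test_that("parsing decomposes the dialect into faithful element tables", {
  p <- parse_pattern("[ILV][ST][ST][ST]N")
  expect_equal(nrow(p$elements), 5L)
  expect_equal(p$elements$kind, c("class", "class", "class", "class", "exact"))
  expect_equal(p$elements$residues[[1]], c("I", "L", "V"))
  expect_equal(p$elements$residues[[5]], "N")
  expect_true(all(p$elements$min_repeat == 1L & p$elements$max_repeat == 1L))

  p2 <- parse_pattern("Ax(9)[PA][AVILFM][MI]x(20,22)[GA][TSNKAH]")
  expect_equal(nrow(p2$elements), 8L)
  expect_equal(p2$elements$kind[2], "wildcard")
  expect_equal(p2$elements$min_repeat[2], 9L)
  expect_equal(p2$elements$max_repeat[2], 9L)
  expect_equal(p2$elements$min_repeat[6], 20L)
  expect_equal(p2$elements$max_repeat[6], 22L)

  # PROSITE-style separators and exclusion classes are normalized
  p3 <- parse_pattern("<G-[DE]-{P}-x(2)>.")
  expect_equal(p3$elements$kind, c("exact", "class", "class", "wildcard"))
  expect_equal(length(p3$elements$residues[[3]]), 19L)
  expect_false("P" %in% p3$elements$residues[[3]])
})

test_that("malformed patterns are rejected with MalformedPattern errors", {
  expect_error(parse_pattern("[ST]x(3,"), class = "tt_malformed_pattern")
  expect_error(parse_pattern("[ST"), class = "tt_malformed_pattern")
  expect_error(parse_pattern("[]N"), class = "tt_malformed_pattern")
  expect_error(parse_pattern("x(5,2)"), class = "tt_malformed_pattern")
  expect_error(parse_pattern("[SB]N"), class = "tt_malformed_pattern")
  expect_error(parse_pattern("aN"), class = "tt_malformed_pattern")
  expect_error(parse_pattern(""), class = "tt_malformed_pattern")
})

test_that("parse -> serialize -> parse is the identity on canonical forms", {
  texts <- c(
    "[ILV][ST][ST][ST]N",
    "[KQ]x(0,1)Dx(0,1)[ST]Dx(3)[ACIMSTV][FILMV]",
    "G[DE][AG]x(24,30)NN",
    "Ax(9)[AP][AFILMV][IM]x(20,22)[AG][AHKNST]"
  )
  for (txt in texts) {
    p <- parse_pattern(txt)
    expect_identical(pattern_to_string(p), txt)
    expect_identical(parse_pattern(pattern_to_string(p))$elements, p$elements)
  }
  # non-canonical input normalizes to the same elements
  expect_identical(
    parse_pattern("[VLI]-[TS][TS][ST]N")$elements,
    parse_pattern("[ILV][ST][ST][ST]N")$elements
  )
})

test_that("pattern bounds are the element-wise repeat sums", {
  expect_equal(
    pattern_bounds(parse_pattern("[ILV][ST][ST][ST]N")),
    tibble::tibble(min_len = 5L, max_len = 5L)
  )
  expect_equal(
    pattern_bounds(parse_pattern("G[DE][GA]x(24,30)NN")),
    tibble::tibble(min_len = 29L, max_len = 35L)
  )
  expect_equal(
    pattern_bounds(parse_pattern("[QK]x(0,1)Dx(0,1)[TS]Dx(3)[ACMVITS][LVIMF]")),
    tibble::tibble(min_len = 9L, max_len = 11L)
  )
})

test_that("scanning reports all distinct windows with exact coordinates", {
  hits <- scan_sequence(parse_pattern("[ILV][ST][ST][ST]N"), "AISSTNA", "toy")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 6L)
  expect_equal(hits$matched_text, "ISSTN")

  # overlap policy: every distinct window is reported
  hits2 <- scan_sequence(parse_pattern("[ST][ST]"), "SSS")
  expect_equal(hits2$start, c(1L, 2L))
  expect_equal(hits2$end, c(2L, 3L))

  expect_equal(nrow(scan_sequence(parse_pattern("[ST]N"), "")), 0L)
  expect_error(
    scan_sequence(parse_pattern("[ST]N"), "AS1TN"),
    class = "tt_invalid_residue"
  )
})

test_that("element spans tile each match and X only matches wildcards", {
  p <- parse_pattern("[QK]x(0,1)D[ST]")
  hits <- scan_sequence(p, "AQDSA")
  expect_equal(nrow(hits), 1L)
  spans <- hits$element_spans[[1]]
  # leftmost-shortest: the optional wildcard takes length 0
  expect_equal(spans$start, c(2L, 3L, 3L, 4L))
  expect_equal(spans$end, c(2L, 2L, 3L, 4L))
  expect_true(all(diff(spans$start) >= 0))

  # X matches the wildcard but never a class or exact element
  expect_equal(nrow(scan_sequence(p, "AQXDS")), 1L)
  expect_equal(nrow(scan_sequence(parse_pattern("[ST]N"), "XN")), 0L)
  expect_equal(nrow(scan_sequence(parse_pattern("SN"), "XN")), 0L)
})

test_that("scan matches a brute-force enumeration oracle on random cases", {
  withr::with_seed(421, {
    for (case in 1:150) {
      p <- parse_pattern(random_pattern_text())
      s <- random_sequence()
      got <- scan_sequence(p, s)[, c("start", "end")]
      want <- oracle_scan(p, s)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  })
})

test_that("match lengths always lie within pattern bounds", {
  withr::with_seed(77, {
    for (case in 1:50) {
      p <- parse_pattern(random_pattern_text())
      s <- random_sequence()
      hits <- scan_sequence(p, s)
      if (nrow(hits) > 0) {
        b <- pattern_bounds(p)
        len <- hits$end - hits$start + 1L
        expect_true(all(len >= b$min_len & len <= b$max_len))
      }
    }
  })
})

test_that("scanning a reversed sequence mirrors coordinates for palindromic patterns", {
  p <- parse_pattern("[ST]x(2)[ST]") # reads the same in both directions
  withr::with_seed(99, {
    for (case in 1:25) {
      s <- random_sequence(25)
      rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      fwd <- scan_sequence(p, s)
      bwd <- scan_sequence(p, rev_s)
      n <- nchar(s)
      mirrored <- tibble::tibble(
        start = sort(n - fwd$end + 1L),
        end = sort(n - fwd$start + 1L)
      )
      expect_equal(as.data.frame(bwd[, c("start", "end")]), as.data.frame(mirrored))
    }
  })
})

test_that("FASTA collections scan in file order and flag duplicate ids", {
  hits <- scan_collection(thiamin_patterns("tpk_thib"), example_fasta())
  expect_equal(hits$sequence_id, "toy_b")
  expect_equal(hits$start, 11L)
  expect_equal(hits$matched_text, "ISSTN")

  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ASSTN", ">a", "VSSTN"), tf)
  expect_warning(
    dup <- scan_collection(parse_pattern("[ILV][ST][ST][ST]N"), tf),
    "Duplicate"
  )
  expect_equal(nrow(dup), 1L) # only the V record matches

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_equal(nrow(scan_collection(thiamin_patterns("tpk"), empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("not fasta at all"), bad)
  expect_error(
    scan_collection(thiamin_patterns("tpk"), bad),
    class = "tt_fasta_parse"
  )
})

test_that("the packaged registry round-trips and matches its own realizations", {
  pats <- thiamin_patterns()
  expect_named(pats, c("tpk", "tpk_thib", "thim", "thdp_motif"))
  withr::with_seed(5, {
    for (p in pats) {
      expect_identical(
        parse_pattern(pattern_to_string(p))$elements, p$elements
      )
      txt <- realize_pattern(p)
      hit <- scan_sequence(p, txt)
      expect_true(any(hit$start == 1L & hit$end == nchar(txt)))
    }
  })
  expect_error(thiamin_patterns("nope"), class = "tt_malformed_pattern")
})
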