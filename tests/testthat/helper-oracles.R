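# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route than the implementation under test.

# Brute-force pattern scan: enumerate every per-element length assignment
# at every start position and collect the distinct (start, end) windows.
oracle_scan <- function(pattern, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  el <- pattern$elements
  n <- length(chars)
  hits <- list()
  recurse <- function(i, pos, start) {
    if (i > nrow(el)) {
      if (pos - 1L >= start) {
        hits[[paste(start, pos - 1L)]] <<- c(start, pos - 1L)
      }
      return(invisible(NULL))
    }
    for (len in el$min_repeat[i]:el$max_repeat[i]) {
      if (pos + len - 1L > n) next
      ok <- if (len == 0L) {
        TRUE
      } else if (el$kind[i] == "wildcard") {
        TRUE
      } else {
        all(chars[pos:(pos + len - 1L)] %in% el$residues[[i]])
      }
      if (ok) recurse(i + 1L, pos + len, start)
    }
  }
  for (s in seq_len(n)) recurse(1L, s, s)
  if (length(hits) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, unname(hits))
  out <- tibble::tibble(start = m[, 1], end = m[, 2])
  dplyr::arrange(dplyr::distinct(out), start, end)
}

# Random pattern text over a small alphabet (kept small so random short
# sequences actually produce matches).
random_pattern_text <- function(max_elements = 6L, max_repeat = 4L,
                                alphabet = c("A", "C", "D", "N", "S", "T")) {
  n_el <- sample(max_elements, 1L)
  parts <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("exact", "class", "wildcard"), 1L)
    core <- switch(kind,
      exact = sample(alphabet, 1L),
      class = paste0(
        "[", paste(sample(alphabet, sample(2:4, 1L)), collapse = ""), "]"
      ),
      wildcard = "x"
    )
    if (kind == "wildcard" && stats::runif(1) < 0.7) {
      lo <- sample(0:max_repeat, 1L)
      hi <- lo + sample(0:(max_repeat - min(lo, max_repeat)), 1L)
      core <- if (lo == hi) {
        paste0(core, "(", lo, ")")
      } else {
        paste0(core, "(", lo, ",", hi, ")")
      }
    }
    core
  }, character(1))
  paste(parts, collapse = "")
}

random_sequence <- function(max_len = 30L,
                            alphabet = c("A", "C", "D", "N", "S", "T")) {
  paste(sample(alphabet, sample(max_len, 1L), replace = TRUE), collapse = "")
}

# Explicit hypergeometric upper-tail sum via binomial-coefficient ratios:
# P(X >= a) for X ~ Hypergeometric(N total, K marked, n drawn).
oracle_hyper_tail <- function(a, K, n, N) {
  ks <- max(0L, a):min(K, n)
  if (a > min(K, n)) return(0)
  sum(exp(
    lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  ))
}

# All-pairs heavy-atom contact search, written directly over the atom table.
oracle_contacts <- function(model, lig_resid, cutoff) {
  at <- model$atoms
  lig <- at[at$record == "HETATM" & at$resid == lig_resid &
    !at$element %in% c("H", "D"), ]
  prot <- at[at$record == "ATOM" & !at$element %in% c("H", "D"), ]
  res <- unique(prot[, c("chain", "resno", "insert", "resid")])
  keep <- logical(nrow(res))
  mind <- numeric(nrow(res))
  for (r in seq_len(nrow(res))) {
    pa <- prot[prot$chain == res$chain[r] & prot$resno == res$resno[r] &
      prot$insert == res$insert[r], ]
    best <- Inf
    for (i in seq_len(nrow(pa))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt(
          (pa$x[i] - lig$x[j])^2 + (pa$y[i] - lig$y[j])^2 +
            (pa$z[i] - lig$z[j])^2
        )
        best <- min(best, d)
      }
    }
    keep[r] <- best <= cutoff
    mind[r] <- best
  }
  out <- res[keep, ]
  out$min_distance <- mind[keep]
  out <- out[order(out$chain, out$resno, out$insert), ]
  tibble::as_tibble(out)
}

# Shared simulation design of the inhibition-recovery studies: generate
# under one rate law with the reference constants and classify.
recover_ki <- function(mechanism, Ki, S_grid, seeds, noise_cv = 0.02) {
  out <- vapply(seeds, function(s) {
    sim <- gen_kinetics(
      mechanism,
      Km = 0.1, Vmax = 1, Ki = Ki,
      S_grid = S_grid, I_grid = assay_grids()$I,
      replicates = 3L, noise_cv = noise_cv, seed = s
    )
    fit <- classify_mechanism(sim$data)
    c(correct = fit$mechanism == mechanism, Ki = fit$Ki)
  }, numeric(2))
  list(accuracy = mean(out["correct", ]), kis = out["Ki", ])
}
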