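#' Sample one realization of a pattern
#'
#' Draws a concrete amino-acid string matching a pattern: each element
#' takes a uniformly sampled repeat length within its bounds and uniformly
#' sampled residues from its class (wildcards draw from the full
#' 20-letter alphabet).
#'
#' @param pattern A `prosite_pattern`.
#' @return A single string.
#' @export
realize_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  el <- pattern$elements
  parts <- vapply(seq_len(nrow(el)), function(i) {
    len <- if (el$min_repeat[i] == el$max_repeat[i]) {
      el$min_repeat[i]
    } else {
      sample(el$min_repeat[i]:el$max_repeat[i], 1L)
    }
    if (len == 0L) {
      return("")
    }
    pool <- if (el$kind[i] == "wildcard") AA20 else el$residues[[i]]
    paste(sample(pool, len, replace = TRUE), collapse = "")
  }, character(1))
  paste(parts, collapse = "")
}

#' Generate sequences with planted pattern instances
#'
#' Background residues are i.i.d. from `background_freqs` (uniform over the
#' 20 amino acids by default, which keeps false-positive expectations
#' closed-form); `k_planted` records each receive one realization of the
#' pattern written at a recorded position. Deterministic under `seed`.
#'
#' @param n Number of records.
#' @param length Sequence length (residues).
#' @param pattern A `prosite_pattern` to plant.
#' @param k_planted Number of records receiving a planted instance
#'   (`<= n`).
#' @param seed Integer seed.
#' @param background_freqs Optional named numeric vector of residue
#'   frequencies over the 20-letter alphabet.
#' @param path Optional FASTA output path.
#' @return List with `sequences` (named character vector), `truth`
#'   (tibble `record_id`, `start`, `end`, `text`), and `seed`.
#' @export
gen_sequences <- function(n, length, pattern, k_planted = 0L, seed = 1L,
                          background_freqs = NULL, path = NULL) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  if (k_planted > n) {
    tt_abort("`k_planted` cannot exceed `n`.", "infeasible_plan")
  }
  b <- pattern_bounds(pattern)
  if (b$min_len > length) {
    tt_abort("Pattern cannot fit in sequences of this length.", "infeasible_plan")
  }
  probs <- if (is.null(background_freqs)) {
    setNames(rep(1 / 20, 20), AA20)
  } else {
    if (!all(AA20 %in% names(background_freqs))) {
      tt_abort("`background_freqs` must cover all 20 residues.", "infeasible_plan")
    }
    background_freqs[AA20] / sum(background_freqs[AA20])
  }
  with_preserved_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(AA20, length, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("synth_%03d", seq_len(n))
    truth <- tibble::tibble(
      record_id = character(0), start = integer(0), end = integer(0),
      text = character(0)
    )
    if (k_planted > 0L) {
      chosen <- sort(sample(n, k_planted))
      planted <- list()
      for (i in chosen) {
        txt <- realize_pattern(pattern)
        # re-draw any realization longer than the record (variable repeats)
        while (nchar(txt) > length) txt <- realize_pattern(pattern)
        start <- sample(length - nchar(txt) + 1L, 1L)
        s <- seqs[[i]]
        substr(s, start, start + nchar(txt) - 1L) <- txt
        seqs[[i]] <- s
        planted[[base::length(planted) + 1L]] <- tibble::tibble(
          record_id = names(seqs)[i],
          start = start,
          end = start + nchar(txt) - 1L,
          text = txt
        )
      }
      truth <- dplyr::bind_rows(planted)
    }
    if (!is.null(path)) {
      write_fasta(seqs, path)
    }
    list(sequences = seqs, truth = truth, seed = seed)
  })
}

#' Write a named character vector as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  lines <- unlist(lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

## Internal-coordinate (NeRF) placement: position d such that |c-d| = bond,
## angle(b,c,d) = `angle` and dihedral(a,b,c,d) = `dihedral` (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  bc <- (c - b) / sqrt(sum((c - b)^2))
  nrm <- cross3(b - a, bc)
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- cross3(nrm, bc)
  c + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

## Standard backbone geometry (config defaults, not claims about any
## particular structure).
backbone_geometry <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
    omega = 180
  )
}

#' Generate an idealized backbone with an optional placed ligand
#'
#' Builds N/CA/C/O backbone coordinates by sequential internal-coordinate
#' construction with standard bond lengths/angles and per-class phi/psi
#' (helix -57/-47, strand -120/+120, loop drawn uniformly from a
#' configurable range outside both boxes), then optionally places a
#' single-atom ligand whose minimum distance to a target residue's atoms
#' equals `ligand_distance` to within 1e-3 angstroms. Deterministic under
#' `seed`; emits PDB-format text that round-trips through
#' [read_structure()].
#'
#' @param segments Data frame (or list coercible to one) with columns
#'   `class` (`"helix"`, `"strand"`, `"loop"`) and `length`.
#' @param ligand_target Residue number near which to place the ligand, or
#'   `NULL` for no ligand.
#' @param ligand_distance Intended minimum heavy-atom distance (angstroms).
#' @param seed Integer seed (used for loop dihedrals).
#' @param loop_phi,loop_psi Sampling ranges for loop dihedrals (degrees);
#'   defaults lie in the left-handed region so loops never classify as
#'   helix or strand.
#' @param chain Chain identifier.
#' @param path Optional output path for the PDB text.
#' @return List with `pdb` (character vector of PDB lines), `truth`
#'   (per-residue tibble `resno`, `class`, `phi`, `psi`, plus the ligand
#'   plan), and `seed`.
#' @export
gen_backbone <- function(segments, ligand_target = NULL, ligand_distance = 3.0,
                         seed = 1L, loop_phi = c(45, 90), loop_psi = c(-30, 60),
                         chain = "A", path = NULL) {
  segments <- tibble::as_tibble(segments)
  if (!all(c("class", "length") %in% names(segments))) {
    tt_abort("`segments` needs class and length columns.", "infeasible_plan")
  }
  if (!all(segments$class %in% c("helix", "strand", "loop"))) {
    tt_abort("Segment classes must be helix, strand or loop.", "infeasible_plan")
  }
  n_res <- sum(segments$length)
  if (n_res < 3L) {
    tt_abort("At least 3 residues are required.", "infeasible_plan")
  }
  geo <- backbone_geometry()
  with_preserved_seed(seed, {
    cls <- rep(segments$class, segments$length)
    phi <- psi <- numeric(n_res)
    for (k in seq_len(n_res)) {
      if (cls[k] == "helix") {
        phi[k] <- -57
        psi[k] <- -47
      } else if (cls[k] == "strand") {
        phi[k] <- -120
        psi[k] <- 120
      } else {
        phi[k] <- runif(1, loop_phi[1], loop_phi[2])
        psi[k] <- runif(1, loop_psi[1], loop_psi[2])
      }
    }

    xyz <- vector("list", n_res) # each: list(N=, CA=, C=, O=)
    N <- c(0, 0, 0)
    CA <- c(geo$b_n_ca, 0, 0)
    th <- geo$a_n_ca_c * pi / 180
    C <- CA + geo$b_ca_c * c(cos(pi - th), sin(pi - th), 0)
    xyz[[1]] <- list(N = N, CA = CA, C = C)
    for (k in seq_len(n_res - 1L)) {
      prev <- xyz[[k]]
      N2 <- place_atom(prev$N, prev$CA, prev$C, geo$b_c_n, geo$a_ca_c_n, psi[k])
      CA2 <- place_atom(prev$CA, prev$C, N2, geo$b_n_ca, geo$a_c_n_ca, geo$omega)
      C2 <- place_atom(prev$C, N2, CA2, geo$b_ca_c, geo$a_n_ca_c, phi[k + 1L])
      xyz[[k + 1L]] <- list(N = N2, CA = CA2, C = C2)
    }
    for (k in seq_len(n_res)) {
      xyz[[k]]$O <- place_atom(
        xyz[[k]]$N, xyz[[k]]$CA, xyz[[k]]$C,
        geo$b_c_o, geo$a_ca_c_o, psi[k] - 180
      )
    }

    lig <- NULL
    if (!is.null(ligand_target)) {
      if (ligand_target < 1L || ligand_target > n_res) {
        tt_abort("`ligand_target` outside the chain.", "infeasible_plan")
      }
      target <- do.call(rbind, xyz[[ligand_target]])
      all_atoms <- do.call(rbind, lapply(xyz, function(r) do.call(rbind, r)))
      ca_t <- xyz[[ligand_target]]$CA
      min_dist_to <- function(p, cloud) {
        min(sqrt(rowSums((cloud - matrix(p, nrow(cloud), 3, byrow = TRUE))^2)))
      }
      place_along <- function(u) {
        u <- u / sqrt(sum(u^2))
        f <- function(t) min_dist_to(ca_t + u * t, target) - ligand_distance
        t_star <- uniroot(f, c(1e-3, ligand_distance + 5), tol = 1e-10)$root
        ca_t + u * t_star
      }
      # candidate outward rays; keep the placement with most clearance
      # from the rest of the chain
      centroid <- colMeans(all_atoms)
      cands <- list(ca_t - centroid, c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))
      cands <- Filter(function(u) sqrt(sum(u^2)) > 1e-9, cands)
      placements <- lapply(cands, place_along)
      clearance <- vapply(placements, min_dist_to, numeric(1), cloud = all_atoms)
      lig <- placements[[which.max(clearance)]]
      if (max(clearance) < 1.5) {
        tt_abort(
          "Ligand placement collides with the backbone (pair < 1.5 angstroms).",
          "geometry_error"
        )
      }
    }

    lines <- character(0)
    serial <- 0L
    for (k in seq_len(n_res)) {
      for (nm in c("N", "CA", "C", "O")) {
        serial <- serial + 1L
        lines <- c(lines, format_pdb_line(
          "ATOM", serial, nm, "ALA", chain, k, xyz[[k]][[nm]],
          element = substr(nm, 1, 1)
        ))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L, "ALA", chain, n_res))
    if (!is.null(lig)) {
      lines <- c(lines, format_pdb_line(
        "HETATM", serial + 2L, "C1", "LIG", chain, n_res + 1L, lig,
        element = "C"
      ))
    }
    lines <- c(lines, "END")
    if (!is.null(path)) writeLines(lines, path)

    truth <- list(
      residues = tibble::tibble(resno = seq_len(n_res), class = cls, phi = phi, psi = psi),
      ligand = if (is.null(lig)) {
        NULL
      } else {
        list(
          target_resno = ligand_target,
          intended_min_distance = ligand_distance,
          xyz = lig
        )
      }
    )
    list(pdb = lines, truth = truth, seed = seed)
  })
}

format_pdb_line <- function(record, serial, name, resname, chain, resno, xyz,
                            occ = 1, b = 0, element = "C") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, name_fmt, "", resname, chain, resno, "",
    xyz[1], xyz[2], xyz[3], occ, b, element
  )
}

#' Generate a noisy initial-rate dataset
#'
#' Evaluates a chosen inhibition rate law over a substrate x inhibitor
#' grid with replicates and multiplicative Gaussian noise
#' `v = v0 (1 + eps)`, `eps ~ N(0, noise_cv)`, redrawn per point while
#' non-positive (truncation to v > 0). Deterministic under `seed`.
#'
#' @inheritParams rate_law
#' @param S_grid,I_grid Substrate and inhibitor concentration grids (mM).
#'   The default inhibitor grid is the six-level design 0, 1, 2.5, 5, 9,
#'   15 mM used for the pyridoxal-kinase inhibition series.
#' @param replicates Replicates per grid point.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return List with `data` (tibble `S`, `I`, `v`, `replicate`) and
#'   `truth` (generating mechanism, parameters, noise level, seed).
#' @export
gen_kinetics <- function(mechanism, Km, Vmax, Ki, Kip = NULL,
                         S_grid = c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6),
                         I_grid = c(0, 1, 2.5, 5, 9, 15),
                         replicates = 3L, noise_cv = 0.02, seed = 1L) {
  mechanism <- match.arg(mechanism, mechanisms())
  if (length(S_grid) == 0L || length(I_grid) == 0L) {
    tt_abort("Concentration grids must be non-empty.", "domain_error")
  }
  if (noise_cv < 0) tt_abort("`noise_cv` must be non-negative.", "domain_error")
  grid <- tidyr::expand_grid(
    S = S_grid, I = I_grid, replicate = seq_len(replicates)
  )
  v0 <- rate_law(grid$S, grid$I, mechanism, Km, Vmax, Ki, Kip)
  with_preserved_seed(seed, {
    v <- v0
    if (noise_cv > 0) {
      v <- v0 * (1 + rnorm(length(v0), 0, noise_cv))
      bad <- which(v <= 0)
      while (length(bad) > 0L) {
        v[bad] <- v0[bad] * (1 + rnorm(length(bad), 0, noise_cv))
        bad <- bad[v[bad] <= 0]
      }
    }
    list(
      data = tibble::tibble(S = grid$S, I = grid$I, v = v, replicate = grid$replicate),
      truth = list(
        mechanism = mechanism, Km = Km, Vmax = Vmax, Ki = Ki, Kip = Kip,
        noise_cv = noise_cv, seed = seed
      )
    )
  })
}

#' Generate paired proteome and annotation tables with known truth
#'
#' Emulates two affinity-eluted proteomes drawn from a common background
#' universe with a controlled overlap, planted known-binder flags at an
#' exact rate, and per-term annotations whose frequency in proteome A is
#' enriched by a chosen factor over the background frequency.
#'
#' @param size_a,size_b Proteome sizes (defaults 150 and 57, the
#'   thiazolium- and thiamin-eluate sizes).
#' @param overlap_fraction Shared fraction of the smaller proteome,
#'   in `[0, 1]`.
#' @param known_binder_fraction Fraction of each proteome flagged `+` in
#'   the known-binder table (planted exactly, not sampled).
#' @param terms Data frame with columns `term`, `background_freq`,
#'   `query_enrichment` (enrichment multiplies the annotation probability
#'   for members of proteome A).
#' @param background_size Size of the id universe.
#' @param seed Integer seed.
#' @return List: `proteome` (tibble `protein_id`, `name`, `thiazolium`,
#'   `thiamin` logical flags), `known_binders` (`+`/`-` flag table),
#'   `annotations` (`protein_id`, `term`), `background` (id vector) and
#'   `truth`.
#' @export
gen_proteomes <- function(size_a = 150L, size_b = 57L, overlap_fraction = 0.5,
                          known_binder_fraction = 0.10, terms = NULL,
                          background_size = 1000L, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1 ||
    known_binder_fraction < 0 || known_binder_fraction > 1) {
    tt_abort("Fractions must lie in [0, 1].", "infeasible_plan")
  }
  n_shared <- round(overlap_fraction * min(size_a, size_b))
  union_size <- size_a + size_b - n_shared
  if (union_size > background_size) {
    tt_abort("Background universe too small for the requested sizes.", "infeasible_plan")
  }
  with_preserved_seed(seed, {
    universe <- sprintf("P%05d", seq_len(background_size))
    ab <- sample(universe, union_size)
    shared <- ab[seq_len(n_shared)]
    a_only <- ab[n_shared + seq_len(size_a - n_shared)]
    b_only <- ab[size_a + seq_len(size_b - n_shared)]
    a_ids <- c(shared, a_only)
    b_ids <- c(shared, b_only)

    proteome <- tibble::tibble(
      protein_id = ab,
      name = paste("synthetic protein", ab),
      thiazolium = ab %in% a_ids,
      thiamin = ab %in% b_ids
    )

    ka <- round(known_binder_fraction * size_a)
    kb <- round(known_binder_fraction * size_b)
    known_a <- sample(a_ids, ka)
    known_b <- sample(b_ids, kb)
    known_ids <- union(known_a, known_b)
    known_binders <- tibble::tibble(
      protein_id = known_ids,
      thiazolium = ifelse(known_ids %in% known_a, "+", "-"),
      thiamin = ifelse(known_ids %in% known_b, "+", "-")
    )

    annotations <- tibble::tibble(protein_id = character(0), term = character(0))
    if (!is.null(terms)) {
      terms <- tibble::as_tibble(terms)
      rows <- lapply(seq_len(nrow(terms)), function(i) {
        p <- rep(terms$background_freq[i], background_size)
        p[universe %in% a_ids] <- min(
          1, terms$background_freq[i] * terms$query_enrichment[i]
        )
        hit <- runif(background_size) < p
        tibble::tibble(protein_id = universe[hit], term = terms$term[i])
      })
      annotations <- dplyr::bind_rows(rows)
    }

    list(
      proteome = proteome,
      known_binders = known_binders,
      annotations = annotations,
      background = universe,
      truth = list(
        a_ids = a_ids, b_ids = b_ids, shared = shared,
        known_a = known_a, known_b = known_b,
        enriched_terms = if (is.null(terms)) {
          character(0)
        } else {
          terms$term[terms$query_enrichment > 1]
        },
        seed = seed
      )
    )
  })
}
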