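#' Read a PDB structure into a minimal model
#'
#' Wraps [bio3d::read.pdb()] and normalizes the result for the pipeline:
#' first model only, waters (`HOH`/`WAT`/`DOD`) dropped, and alternate
#' locations resolved per atom to the highest-occupancy record (ties go to
#' the lexicographically first altloc, i.e. `A`).
#'
#' @param path Path to a PDB-format file containing at least one `ATOM`
#'   record.
#' @param id Model identifier; defaults to the file name without extension.
#' @return A `structure_model`: a list with `id` and an `atoms` tibble
#'   (`record`, `chain`, `resno`, `insert`, `resid`, `elety`, `element`,
#'   `x`, `y`, `z`, `occupancy`, `alt`). Protein residues come from `ATOM`
#'   records; hetero groups (ligands) from `HETATM`.
#' @export
read_structure <- function(path, id = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    tt_abort("`path` must name an existing PDB file.", "structure_parse")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      tt_abort(
        paste0("Failed to parse PDB '", path, "': ", conditionMessage(e)),
        "structure_parse"
      )
    }
  )
  at <- tibble::as_tibble(pdb$atom)
  if (!any(at$type == "ATOM")) {
    tt_abort("No ATOM records in PDB input.", "structure_parse")
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    tt_abort("Non-finite coordinates in PDB input.", "structure_parse")
  }
  at <- dplyr::filter(at, !.data$resid %in% c("HOH", "WAT", "DOD"))
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  elem <- at$elesy
  elem <- ifelse(
    is.na(elem) | elem == "",
    toupper(substr(gsub("[0-9' ]", "", at$elety), 1, 1)),
    toupper(trimws(elem))
  )
  at$element <- elem
  # altloc resolution: highest occupancy, ties -> first altloc code
  at <- at |>
    dplyr::group_by(.data$type, .data$chain, .data$resno, .data$insert, .data$resid, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert, .data$eleno)

  atoms <- tibble::tibble(
    record = at$type,
    chain = at$chain,
    resno = as.integer(at$resno),
    insert = at$insert,
    resid = at$resid,
    elety = trimws(at$elety),
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    alt = at$alt
  )
  structure(
    list(
      id = id %||% sub("\\.[^.]*$", "", basename(path)),
      atoms = atoms
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  prot <- dplyr::filter(x$atoms, .data$record == "ATOM")
  het <- hetero_groups(x)
  cat(
    "<structure_model ", x$id, "> ",
    dplyr::n_distinct(prot$chain, prot$resno, prot$insert), " residues, ",
    nrow(het), " hetero group(s), ", nrow(x$atoms), " atoms\n",
    sep = ""
  )
  invisible(x)
}

#' Hetero groups (candidate ligands) of a model
#'
#' @param model A `structure_model`.
#' @return Tibble with one row per `HETATM` residue: `resid`, `chain`,
#'   `resno`, `n_atoms`.
#' @export
hetero_groups <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  model$atoms |>
    dplyr::filter(.data$record == "HETATM") |>
    dplyr::count(.data$resid, .data$chain, .data$resno, name = "n_atoms")
}

#' One-letter sequence of a chain
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @return Single string; non-standard residues become `X`.
#' @export
chain_sequence <- function(model, chain = "A") {
  stopifnot(inherits(model, "structure_model"))
  res <- model$atoms |>
    dplyr::filter(.data$record == "ATOM", .data$chain == !!chain) |>
    dplyr::distinct(.data$resno, .data$insert, .data$resid) |>
    dplyr::arrange(.data$resno, .data$insert)
  if (nrow(res) == 0L) {
    tt_abort(paste0("No protein residues in chain '", chain, "'."), "empty_selection")
  }
  aa1 <- suppressWarnings(bio3d::aa321(res$resid))
  aa1[is.na(aa1) | !aa1 %in% AA20] <- "X"
  paste(aa1, collapse = "")
}

#' Ligand selection
#'
#' @param resid 3-letter HET code (e.g. `"TPP"`, `"NDP"`).
#' @param chain Chain id, or `NULL` for any chain.
#' @param resno Residue number, or `NULL` for any.
#' @return A `ligand_selection` list.
#' @export
ligand_selection <- function(resid, chain = NULL, resno = NULL) {
  structure(
    list(resid = resid, chain = chain, resno = resno),
    class = "ligand_selection"
  )
}

heavy_atoms <- function(atoms) {
  dplyr::filter(atoms, !.data$element %in% c("H", "D"))
}

resolve_ligand <- function(model, ligand) {
  if (!inherits(ligand, "ligand_selection")) {
    if (is.character(ligand) && length(ligand) == 1L) {
      ligand <- ligand_selection(ligand)
    } else {
      tt_abort("`ligand` must be a ligand_selection or a HET code.", "ligand_not_found")
    }
  }
  at <- dplyr::filter(model$atoms, .data$record == "HETATM", .data$resid == ligand$resid)
  if (!is.null(ligand$chain)) {
    at <- dplyr::filter(at, .data$chain == ligand$chain)
  }
  if (!is.null(ligand$resno)) {
    at <- dplyr::filter(at, .data$resno == ligand$resno)
  }
  if (nrow(at) == 0L) {
    tt_abort(
      paste0("Ligand '", ligand$resid, "' not found in model."),
      "ligand_not_found"
    )
  }
  at
}

## Minimum distance from each row of `xyz_a` to the point cloud `xyz_b`.
min_dist_to_set <- function(xyz_a, xyz_b) {
  vapply(seq_len(nrow(xyz_a)), function(i) {
    d2 <- (xyz_b[, 1] - xyz_a[i, 1])^2 +
      (xyz_b[, 2] - xyz_a[i, 2])^2 +
      (xyz_b[, 3] - xyz_a[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

#' Protein residues in contact with a ligand
#'
#' Every protein residue with any heavy atom within `cutoff` angstroms of
#' any ligand heavy atom, with the per-residue minimum heavy-atom distance.
#' Hydrogens are ignored. An empty result is a valid return (no contacts at
#' that cutoff), not an error.
#'
#' @param model A `structure_model`.
#' @param ligand A [ligand_selection()] or HET code string.
#' @param cutoff Distance cutoff in angstroms (default 4.0, a conventional
#'   polar/van-der-Waals contact threshold).
#' @return Tibble (`chain`, `resno`, `insert`, `resid`, `min_distance`)
#'   ordered by chain then residue number.
#' @export
find_ligand_contacts <- function(model, ligand, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    tt_abort("`cutoff` must be a positive distance in angstroms.", "domain_error")
  }
  lig <- heavy_atoms(resolve_ligand(model, ligand))
  prot <- heavy_atoms(dplyr::filter(model$atoms, .data$record == "ATOM"))
  if (nrow(lig) == 0L || nrow(prot) == 0L) {
    tt_abort("No heavy atoms available for the contact search.", "empty_selection")
  }
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  prot$min_atom_dist <- min_dist_to_set(as.matrix(prot[, c("x", "y", "z")]), lig_xyz)
  prot |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid) |>
    dplyr::summarise(min_distance = min(.data$min_atom_dist), .groups = "drop") |>
    dplyr::filter(.data$min_distance <= cutoff) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
}

#' Minimum heavy-atom distance between two selections
#'
#' The measure used to relate a candidate binding pattern to a known site:
#' the minimum over all heavy-atom pairs between the two selections.
#'
#' @param model A `structure_model`.
#' @param residues Tibble/data frame with `chain` and `resno` columns
#'   selecting protein residues.
#' @param site A second selection: either a [ligand_selection()] (or HET
#'   code) or another residue table.
#' @param strict If the two selections share atoms: error when `TRUE`
#'   (default), else return 0.
#' @return Distance in angstroms.
#' @export
min_site_distance <- function(model, residues, site, strict = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  a <- heavy_atoms(residue_atoms(model, residues))
  b <- if (inherits(site, "ligand_selection") ||
    (is.character(site) && length(site) == 1L)) {
    heavy_atoms(resolve_ligand(model, site))
  } else {
    heavy_atoms(residue_atoms(model, site))
  }
  if (nrow(a) == 0L || nrow(b) == 0L) {
    tt_abort("Empty selection in distance computation.", "empty_selection")
  }
  key <- function(at) paste(at$record, at$chain, at$resno, at$insert, at$elety)
  if (any(key(a) %in% key(b))) {
    if (strict) {
      tt_abort("Selections overlap; distance is degenerate.", "empty_selection")
    }
    return(0)
  }
  min(min_dist_to_set(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")])))
}

residue_atoms <- function(model, residues) {
  residues <- tibble::as_tibble(residues)
  if (!all(c("chain", "resno") %in% names(residues))) {
    tt_abort("Residue selections need `chain` and `resno` columns.", "empty_selection")
  }
  dplyr::semi_join(
    dplyr::filter(model$atoms, .data$record == "ATOM"),
    residues,
    by = c("chain", "resno")
  )
}

#' Map a sequence-pattern match onto structure residues
#'
#' @param match One match: a one-row tibble from [scan_sequence()] or a
#'   list with `start` and `end`.
#' @param model A `structure_model`.
#' @param numbering_map Either a data frame with columns `seq_pos`, `chain`,
#'   `resno` covering `match$start:match$end`, or a single integer offset
#'   (resno = seq_pos + offset, with `chain` giving the chain).
#' @param chain Chain used with an offset-style `numbering_map`.
#' @param strict Error (`MappingGap`) if a matched position maps to no
#'   resolved residue; default `FALSE` lists it as unresolved instead.
#' @return Tibble (`seq_pos`, `chain`, `resno`, `resid`, `resolved`).
#' @export
map_match_to_structure <- function(match, model, numbering_map = 0L,
                                   chain = "A", strict = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  start <- as.integer(match$start[1])
  end <- as.integer(match$end[1])
  pos <- start:end
  if (is.data.frame(numbering_map)) {
    nm <- tibble::as_tibble(numbering_map)
    if (!all(c("seq_pos", "chain", "resno") %in% names(nm))) {
      tt_abort("`numbering_map` needs seq_pos, chain, resno columns.", "mapping_gap")
    }
    mapped <- dplyr::left_join(tibble::tibble(seq_pos = pos), nm, by = "seq_pos")
    if (any(is.na(mapped$resno))) {
      tt_abort("`numbering_map` does not cover the full match.", "mapping_gap")
    }
  } else {
    mapped <- tibble::tibble(
      seq_pos = pos,
      chain = chain,
      resno = pos + as.integer(numbering_map)
    )
  }
  res <- model$atoms |>
    dplyr::filter(.data$record == "ATOM") |>
    dplyr::distinct(.data$chain, .data$resno, .data$resid)
  out <- dplyr::left_join(mapped, res, by = c("chain", "resno")) |>
    dplyr::mutate(resolved = !is.na(.data$resid))
  if (strict && any(!out$resolved)) {
    tt_abort(
      paste0(
        "Matched position(s) map to no resolved residue: ",
        paste(out$seq_pos[!out$resolved], collapse = ", ")
      ),
      "mapping_gap"
    )
  }
  out
}

#' Torsion (dihedral) angle of four points
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  x <- sum(c12 * c23)
  y <- sum(cross3(c12, c23) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Ramachandran classification boxes
#'
#' Default phi/psi boxes: helix phi in \[-100, -30\], psi in \[-80, -5\];
#' strand phi in \[-170, -70\], psi in \[90, 180\] or \[-180, -170\];
#' everything else classified loop.
#'
#' @return A list of class boxes consumed by [assess_conformation()].
#' @export
ramachandran_boxes <- function() {
  list(
    helix = list(phi = c(-100, -30), psi = list(c(-80, -5))),
    strand = list(phi = c(-170, -70), psi = list(c(90, 180), c(-180, -170)))
  )
}

classify_phipsi <- function(phi, psi, boxes = ramachandran_boxes()) {
  in_ranges <- function(v, ranges) {
    any(vapply(ranges, function(r) v >= r[1] & v <= r[2], logical(1)))
  }
  mapply(function(f, s) {
    if (is.na(f) || is.na(s)) {
      return("undefined")
    }
    for (cls in names(boxes)) {
      b <- boxes[[cls]]
      if (f >= b$phi[1] && f <= b$phi[2] && in_ranges(s, b$psi)) {
        return(cls)
      }
    }
    "loop"
  }, phi, psi, USE.NAMES = FALSE)
}

backbone_xyz <- function(model, chain, resno, elety) {
  at <- dplyr::filter(
    model$atoms, .data$record == "ATOM", .data$chain == !!chain,
    .data$resno == !!resno, .data$elety == !!elety
  )
  if (nrow(at) == 0L) {
    return(NULL)
  }
  c(at$x[1], at$y[1], at$z[1])
}

#' Backbone conformation of a residue segment
#'
#' Computes phi/psi from the backbone dihedrals (phi: C(i-1)-N-CA-C; psi:
#' N-CA-C-N(i+1)) and classifies each residue by configurable Ramachandran
#' boxes. Residues lacking a neighbour for a dihedral (segment/chain
#' termini, chain breaks) are `undefined` and excluded from the class
#' fractions; the majority class is taken over classified residues with
#' ties going to `loop`.
#'
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @param start,end First and last residue number of the segment.
#' @param boxes Ramachandran boxes, see [ramachandran_boxes()].
#' @return A `conformation_assessment`: list with a per-residue tibble
#'   (`chain`, `resno`, `resid`, `phi`, `psi`, `class`), `majority_class`
#'   and `class_fractions`.
#' @export
assess_conformation <- function(model, chain = "A", start, end,
                                boxes = ramachandran_boxes()) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$atoms |>
    dplyr::filter(.data$record == "ATOM", .data$chain == !!chain) |>
    dplyr::distinct(.data$resno, .data$resid) |>
    dplyr::arrange(.data$resno)
  seg <- dplyr::filter(res, .data$resno >= start, .data$resno <= end)
  if (nrow(seg) == 0L) {
    tt_abort("Segment contains no residues.", "empty_selection")
  }
  for (rn in seg$resno) {
    for (a in c("N", "CA", "C")) {
      if (is.null(backbone_xyz(model, chain, rn, a))) {
        tt_abort(
          paste0("Residue ", rn, " lacks backbone atom ", a, "."),
          "missing_backbone"
        )
      }
    }
  }
  has_res <- function(rn) rn %in% res$resno &&
    !is.null(backbone_xyz(model, chain, rn, "N")) &&
    !is.null(backbone_xyz(model, chain, rn, "CA")) &&
    !is.null(backbone_xyz(model, chain, rn, "C"))

  phi <- psi <- rep(NA_real_, nrow(seg))
  for (k in seq_len(nrow(seg))) {
    rn <- seg$resno[k]
    if (has_res(rn - 1L)) {
      phi[k] <- torsion_angle(
        backbone_xyz(model, chain, rn - 1L, "C"),
        backbone_xyz(model, chain, rn, "N"),
        backbone_xyz(model, chain, rn, "CA"),
        backbone_xyz(model, chain, rn, "C")
      )
    }
    if (has_res(rn + 1L)) {
      psi[k] <- torsion_angle(
        backbone_xyz(model, chain, rn, "N"),
        backbone_xyz(model, chain, rn, "CA"),
        backbone_xyz(model, chain, rn, "C"),
        backbone_xyz(model, chain, rn + 1L, "N")
      )
    }
  }
  cls <- classify_phipsi(phi, psi, boxes)
  residues <- tibble::tibble(
    chain = chain, resno = seg$resno, resid = seg$resid,
    phi = phi, psi = psi, class = cls
  )
  classified <- cls[cls != "undefined"]
  fractions <- if (length(classified) > 0L) {
    table(factor(classified, levels = c("helix", "strand", "loop"))) / length(classified)
  } else {
    table(factor(character(0), levels = c("helix", "strand", "loop")))
  }
  counts <- table(factor(classified, levels = c("helix", "strand", "loop")))
  majority <- if (length(classified) == 0L) {
    "undefined"
  } else {
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1L) "loop" else top
  }
  structure(
    list(
      segment = list(chain = chain, start = start, end = end),
      residues = residues,
      majority_class = majority,
      class_fractions = as.numeric(fractions) |> setNames(names(fractions))
    ),
    class = "conformation_assessment"
  )
}

#' @export
print.conformation_assessment <- function(x, ...) {
  cat(
    "<conformation_assessment> chain ", x$segment$chain, " ",
    x$segment$start, "-", x$segment$end, ": majority ", x$majority_class, "\n",
    sep = ""
  )
  fr <- x$class_fractions
  cat(paste0(names(fr), " ", sprintf("%.2f", fr), collapse = ", "), "\n")
  invisible(x)
}

#' Generalize ligand contacts into a sequence pattern
#'
#' Turns an ordered ligand-contact residue list into a PROSITE-dialect
#' pattern: each contact becomes a residue position and each sequence gap of
#' length g between consecutive contacts becomes a wildcard `x(g)`. With a
#' multiple sequence alignment of homologs, each position's residue set is
#' widened to the residues observed in the corresponding alignment column
#' (gaps ignored) and the wildcard ranges to the min/max gap observed
#' across rows.
#'
#' Contacts spanning several chains (e.g. a trimer interface site) yield
#' one pattern per chain plus a cross-chain note, since a linear sequence
#' pattern cannot span chains.
#'
#' @param contacts Tibble from [find_ligand_contacts()] (needs `chain`,
#'   `resno`, `resid`).
#' @param sequence The chain's one-letter sequence (the contact `resno`
#'   values are interpreted as positions in it after subtracting `offset`).
#' @param alignment Optional aligned FASTA: path, `AAStringSet`, or named
#'   character vector, one row of which degaps to `sequence`.
#' @param offset Numbering offset: sequence position = resno - offset.
#' @param id Pattern id for the derived pattern.
#' @return For single-chain contacts, a `motif_template`: list with
#'   `positions`, `residue_sets`, `gaps` and the derived `pattern`
#'   (a `prosite_pattern`). For multi-chain contacts, a named list of
#'   per-chain templates with attribute `cross_chain_note`.
#' @export
contacts_to_pattern <- function(contacts, sequence, alignment = NULL,
                                offset = 0L, id = "derived") {
  contacts <- tibble::as_tibble(contacts)
  if (nrow(contacts) == 0L) {
    tt_abort("Empty contact list.", "empty_contacts")
  }
  chains <- unique(contacts$chain)
  if (length(chains) > 1L) {
    out <- lapply(chains, function(ch) {
      contacts_to_pattern(
        dplyr::filter(contacts, .data$chain == ch),
        sequence,
        alignment = alignment, offset = offset,
        id = paste0(id, "_", ch)
      )
    })
    names(out) <- chains
    attr(out, "cross_chain_note") <- paste0(
      "Contacts span chains ", paste(chains, collapse = ", "),
      "; one linear pattern emitted per chain."
    )
    rlang::warn(attr(out, "cross_chain_note"))
    return(out)
  }

  chars <- strsplit(toupper(sequence), "")[[1]]
  pos <- sort(unique(contacts$resno)) - as.integer(offset)
  if (any(pos < 1L | pos > length(chars))) {
    tt_abort("Contact positions fall outside the sequence.", "mapping_gap")
  }

  if (is.null(alignment)) {
    residue_sets <- lapply(pos, function(p) chars[p])
    gaps <- tibble::tibble(
      after = utils::head(pos, -1L),
      min_gap = diff(pos) - 1L,
      max_gap = diff(pos) - 1L
    )
  } else {
    rows <- read_fasta_sequences(alignment)
    degapped <- gsub("[-.]", "", toupper(rows))
    hit <- which(degapped == paste(chars, collapse = ""))
    if (length(hit) == 0L) {
      tt_abort(
        "The chain sequence is not a row of the alignment.",
        "alignment_mismatch"
      )
    }
    ref <- strsplit(toupper(rows[[hit[1]]]), "")[[1]]
    # map sequence positions -> alignment columns of the reference row
    col_of_pos <- which(!ref %in% c("-", "."))
    cols <- col_of_pos[pos]
    aln_mat <- do.call(rbind, strsplit(toupper(unname(rows)), ""))
    residue_sets <- lapply(cols, function(cl) {
      obs <- setdiff(unique(aln_mat[, cl]), c("-", ".", "X"))
      obs <- intersect(obs, AA20)
      if (length(obs) == 0L) {
        tt_abort("Alignment column holds no standard residue.", "alignment_mismatch")
      }
      sort(obs)
    })
    if (length(cols) > 1L) {
      gap_counts <- vapply(seq_len(length(cols) - 1L), function(k) {
        if (cols[k + 1L] - cols[k] <= 1L) {
          return(rep(0L, nrow(aln_mat)))
        }
        between <- aln_mat[, (cols[k] + 1L):(cols[k + 1L] - 1L), drop = FALSE]
        as.integer(rowSums(matrix(
          !between %in% c("-", "."),
          nrow = nrow(between)
        )))
      }, integer(nrow(aln_mat)))
      gap_counts <- matrix(gap_counts, nrow = nrow(aln_mat))
      gaps <- tibble::tibble(
        after = utils::head(pos, -1L),
        min_gap = as.integer(apply(gap_counts, 2L, min)),
        max_gap = as.integer(apply(gap_counts, 2L, max))
      )
    } else {
      gaps <- tibble::tibble(
        after = integer(0), min_gap = integer(0), max_gap = integer(0)
      )
    }
  }

  parts <- character(0)
  for (k in seq_along(pos)) {
    set <- residue_sets[[k]]
    parts <- c(
      parts,
      if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
    )
    if (k < length(pos)) {
      mn <- gaps$min_gap[k]
      mx <- gaps$max_gap[k]
      if (mx > 0L) {
        parts <- c(
          parts,
          if (mn == mx) paste0("x(", mn, ")") else paste0("x(", mn, ",", mx, ")")
        )
      }
    }
  }
  pattern <- parse_pattern(
    paste(parts, collapse = ""),
    id = id,
    source_note = paste0(
      "derived from ligand contacts at positions ",
      paste(pos, collapse = ",")
    )
  )
  structure(
    list(
      chain = chains,
      positions = pos,
      residue_sets = residue_sets,
      gaps = gaps,
      pattern = pattern
    ),
    class = "motif_template"
  )
}

#' @export
print.motif_template <- function(x, ...) {
  cat(
    "<motif_template> chain ", x$chain, ", positions ",
    paste(x$positions, collapse = ","), "\n  pattern: ",
    pattern_to_string(x$pattern), "\n",
    sep = ""
  )
  invisible(x)
}
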