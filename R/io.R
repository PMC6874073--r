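#' @keywords internal
expected_units <- list(energy = "kcal/mol", wavenumber = "cm-1", rho = "au")

ref_kinetics_cols <- c("ddG_reverse", "ddE_reverse", "k_forward", "k_reverse",
                       "tau_999", "tau_lifetime")
ref_contact_cols <- c("energy", "formula_mark", "flag_inconsistent")

empty_ref_kinetics <- function() {
  tibble::as_tibble(c(list(name = character()),
                      stats::setNames(rep(list(double()), 6),
                                      ref_kinetics_cols)))
}

empty_ref_contacts <- function() {
  tibble::tibble(structure_label = character(), donor_label = character(),
                 acceptor_label = character(), energy = double(),
                 formula_mark = character(), flag_inconsistent = logical())
}

# all-NA columns deserialise as logical; coerce to the canonical schema
coerce_cols <- function(tbl, proto) {
  for (col in intersect(names(tbl), names(proto))) {
    cast <- switch(class(proto[[col]])[1],
                   character = as.character, numeric = as.double,
                   logical = as.logical, identity)
    tbl[[col]] <- cast(tbl[[col]])
  }
  tbl
}

infer_dialect <- function(path, dialect) {
  if (!is.null(dialect)) return(match.arg(dialect, c("json", "tsv")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
}

#' Read a reaction set from disk
#'
#' Two dialects are supported. `json`: a single file with top-level keys
#' `units`, `reference_label`, `metadata`, `reactions`, `structures` (each
#' structure carrying its nested `contacts`) and a separate `reference` block
#' for printed annotations. `tsv`: `path` is a stem; `<stem>.reactions.tsv`
#' and `<stem>.contacts.tsv` hold one reactions table and one contacts table
#' (structure-level columns repeated on each contact row; a structure with no
#' contacts appears once with blank contact fields), units and the reference
#' label declared in `#`-comment headers. Declared units must match the
#' package's convention (energies kcal/mol, wavenumbers cm^-1, densities
#' a.u.); anything else is rejected.
#'
#' @param path File path (json) or stem (tsv).
#' @param dialect `"json"` or `"tsv"`; inferred from the extension when
#'   `NULL`.
#' @return A validated [reaction_set()].
#' @export
read_reaction_set <- function(path, dialect = NULL) {
  dialect <- infer_dialect(path, dialect)
  if (dialect == "json") read_rs_json(path) else read_rs_tsv(path)
}

#' Write a reaction set to disk
#'
#' Inverse of [read_reaction_set()]; a round-trip through either dialect
#' reproduces the set field-for-field. Numbers are written as plain decimal
#' literals at full precision (scientific notation like `3.09e-58` where
#' shorter).
#'
#' @param rs A [reaction_set()].
#' @inheritParams read_reaction_set
#' @return `rs`, invisibly.
#' @export
write_reaction_set <- function(rs, path, dialect = NULL) {
  stopifnot(inherits(rs, "reaction_set"))
  dialect <- infer_dialect(path, dialect)
  if (dialect == "json") write_rs_json(rs, path) else write_rs_tsv(rs, path)
  invisible(rs)
}

# ---- JSON dialect ----------------------------------------------------------

read_rs_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = FALSE)
  check_units(doc$units)
  reactions <- if (is.null(doc$reactions) || length(doc$reactions) == 0) {
    empty_reactions()
  } else {
    coerce_cols(tibble::as_tibble(doc$reactions), empty_reactions())
  }
  structures <- empty_structures()
  contacts <- empty_contacts()
  if (!is.null(doc$structures) && length(doc$structures) > 0) {
    stbl <- tibble::as_tibble(doc$structures)
    nested <- stbl$contacts
    stbl$contacts <- NULL
    structures <- coerce_cols(stbl, empty_structures())
    rows <- purrr::imap(nested, function(ct, i) {
      if (is.null(ct) || length(ct) == 0) return(NULL)
      dplyr::mutate(tibble::as_tibble(ct),
                    structure_label = stbl$label[[i]], .before = 1)
    })
    rows <- purrr::compact(rows)
    if (length(rows) > 0) {
      contacts <- dplyr::bind_rows(rows)
      for (col in names(empty_contacts())) {
        if (!col %in% names(contacts)) contacts[[col]] <- NA_real_
      }
      contacts <- coerce_cols(contacts[names(empty_contacts())],
                              empty_contacts())
    }
  }
  reference <- list(kinetics = empty_ref_kinetics(),
                    contacts = empty_ref_contacts())
  if (!is.null(doc$reference)) {
    if (!is.null(doc$reference$kinetics) &&
        length(doc$reference$kinetics) > 0) {
      reference$kinetics <- coerce_cols(
        tibble::as_tibble(doc$reference$kinetics), empty_ref_kinetics())
    }
    if (!is.null(doc$reference$contacts) &&
        length(doc$reference$contacts) > 0) {
      reference$contacts <- coerce_cols(
        tibble::as_tibble(doc$reference$contacts), empty_ref_contacts())
    }
  }
  reaction_set(
    reactions = reactions, structures = structures, contacts = contacts,
    reference = reference,
    reference_label = doc$reference_label %||% NA_character_,
    metadata = as.list(doc$metadata %||% list())
  )
}

write_rs_json <- function(rs, path) {
  st <- rs$structures
  nested <- purrr::map(seq_len(nrow(st)), function(i) {
    ct <- dplyr::filter(rs$contacts, .data$structure_label == st$label[[i]])
    ct$structure_label <- NULL
    ct
  })
  structures <- if (nrow(st) > 0) {
    dplyr::mutate(st, contacts = nested)
  } else {
    list()
  }
  doc <- list(
    units = expected_units,
    reference_label = rs$reference_label,
    metadata = rs$metadata,
    reactions = rs$reactions,
    structures = structures,
    reference = rs$reference
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
}

check_units <- function(units) {
  if (is.null(units)) stop("file declares no units block", call. = FALSE)
  for (key in names(expected_units)) {
    got <- units[[key]]
    if (is.null(got) || !identical(got, expected_units[[key]])) {
      stop(sprintf("declared unit for %s is '%s'; this package requires '%s'",
                   key, got %||% "<absent>", expected_units[[key]]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- TSV dialect -----------------------------------------------------------

tsv_paths <- function(stem) {
  stem <- sub("\\.(reactions|contacts)\\.tsv$", "", stem)
  list(reactions = paste0(stem, ".reactions.tsv"),
       contacts = paste0(stem, ".contacts.tsv"))
}

tsv_header <- function(rs) {
  meta <- ""
  if (length(rs$metadata) > 0) {
    meta <- paste0("# metadata: ",
                   paste(names(rs$metadata), unlist(rs$metadata),
                         sep = "=", collapse = "\t"))
  }
  c("# units: energy=kcal/mol wavenumber=cm-1 rho=au",
    paste0("# reference_label: ",
           ifelse(is.na(rs$reference_label), "", rs$reference_label)),
    if (nzchar(meta)) meta)
}

write_rs_tsv <- function(rs, stem) {
  paths <- tsv_paths(stem)
  rx <- rs$reactions
  refk <- rs$reference$kinetics %||% empty_ref_kinetics()
  if (nrow(refk) > 0) {
    names(refk)[-1] <- paste0("ref_", names(refk)[-1])
    rx <- dplyr::left_join(rx, refk, by = "name")
  }
  writeLines(c(tsv_header(rs), readr::format_tsv(rx)), paths$reactions)

  st <- rs$structures
  ct <- rs$contacts
  refc <- rs$reference$contacts %||% empty_ref_contacts()
  if (nrow(refc) > 0) {
    names(refc)[-(1:3)] <- paste0("ref_", names(refc)[-(1:3)])
    ct <- dplyr::left_join(
      ct, refc, by = c("structure_label", "donor_label", "acceptor_label"))
  }
  joined <- dplyr::left_join(st, ct,
                             by = c(label = "structure_label"))
  writeLines(c(tsv_header(rs), readr::format_tsv(joined)), paths$contacts)
}

parse_tsv_header <- function(path) {
  lines <- readLines(path, n = 10)
  comments <- lines[startsWith(lines, "#")]
  units_line <- comments[startsWith(comments, "# units:")]
  if (length(units_line) == 0) stop("file declares no units block", call. = FALSE)
  pairs <- strsplit(trimws(sub("# units:", "", units_line[1])), "\\s+")[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  units <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  check_units(units)
  ref_line <- comments[startsWith(comments, "# reference_label:")]
  reference_label <- if (length(ref_line) > 0) {
    val <- trimws(sub("# reference_label:", "", ref_line[1]))
    if (nzchar(val)) val else NA_character_
  } else {
    NA_character_
  }
  meta_line <- comments[startsWith(comments, "# metadata:")]
  metadata <- list()
  if (length(meta_line) > 0) {
    pairs <- strsplit(trimws(sub("# metadata:", "", meta_line[1])), "\t")[[1]]
    kv <- strsplit(pairs, "=", fixed = TRUE)
    metadata <- stats::setNames(
      lapply(kv, function(p) paste(p[-1], collapse = "=")),
      vapply(kv, `[`, "", 1))
  }
  list(reference_label = reference_label, metadata = metadata)
}

read_rs_tsv <- function(stem) {
  paths <- tsv_paths(stem)
  if (!file.exists(paths$reactions)) {
    stop("no such file: ", paths$reactions, call. = FALSE)
  }
  hdr <- parse_tsv_header(paths$reactions)
  rx <- readr::read_tsv(paths$reactions, comment = "#",
                        show_col_types = FALSE,
                        col_types = readr::cols(
                          name = readr::col_character(),
                          name_ascii = readr::col_character(),
                          reactant = readr::col_character(),
                          ts = readr::col_character(),
                          product = readr::col_character(),
                          .default = readr::col_double()
                        ))
  refk <- empty_ref_kinetics()
  ref_cols <- paste0("ref_", ref_kinetics_cols)
  if (any(ref_cols %in% names(rx))) {
    present <- intersect(ref_cols, names(rx))
    refk <- rx[c("name", present)]
    names(refk) <- sub("^ref_", "", names(refk))
    rx <- rx[setdiff(names(rx), present)]
  }

  char_cols <- c("label", "role", "donor_label", "acceptor_label",
                 "contact_class", "ref_formula_mark")
  present <- names(readr::read_tsv(paths$contacts, comment = "#", n_max = 0,
                                   show_col_types = FALSE))
  spec <- c(
    stats::setNames(rep(list(readr::col_character()),
                        sum(char_cols %in% present)),
                    intersect(char_cols, present)),
    if ("ref_flag_inconsistent" %in% present) {
      list(ref_flag_inconsistent = readr::col_logical())
    }
  )
  joined <- readr::read_tsv(paths$contacts, comment = "#",
                            show_col_types = FALSE,
                            col_types = do.call(
                              readr::cols,
                              c(spec, .default = list(readr::col_double()))))
  st_cols <- names(empty_structures())
  structures <- dplyr::distinct(
    dplyr::rename(joined[intersect(c("label", st_cols), names(joined))],
                  label = "label"))
  ct <- dplyr::rename(joined, structure_label = "label")
  ct <- ct[!is.na(ct$donor_label), , drop = FALSE]
  refc <- empty_ref_contacts()
  if ("ref_energy" %in% names(ct) && nrow(ct) > 0) {
    refc <- ct[c("structure_label", "donor_label", "acceptor_label",
                 intersect(paste0("ref_", ref_contact_cols), names(ct)))]
    names(refc) <- sub("^ref_", "", names(refc))
    refc <- refc[!is.na(refc$energy), , drop = FALSE]
  }
  keep <- intersect(names(empty_contacts()), names(ct))
  contacts <- if (nrow(ct) > 0) ct[keep] else empty_contacts()
  reaction_set(
    reactions = if (nrow(rx) > 0) rx else empty_reactions(),
    structures = if (nrow(structures) > 0 &&
                     !all(is.na(structures$label))) structures else
                       empty_structures(),
    contacts = contacts,
    reference = list(kinetics = refk, contacts = refc),
    reference_label = hdr$reference_label,
    metadata = hdr$metadata
  )
}
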