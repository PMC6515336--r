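#' @keywords internal
"_PACKAGE"

LABELS <- c("positive", "negative", "unknown")
TIERS <- c("tier1", "tier2")
STATUSES <- c("active", "rejected_structure", "rejected_size",
              "rejected_conflict", "rejected_vote")

RECORD_COLUMNS <- c("compound_id", "smiles", "canonical_key", "label",
                    "source_tier", "source_name", "status", "reason")

#' Build a table of compound records
#'
#' A compound record ties one structure (SMILES) to its hepatotoxicity label
#' and provenance. Records are held in a plain `data.frame` with a fixed set
#' of columns; every pipeline stage consumes and returns this shape.
#'
#' @param compound_id character vector of unique identifiers.
#' @param smiles character vector of SMILES strings as supplied upstream.
#' @param label labels in any accepted dialect: `1`/`0`, `pos`/`neg`,
#'   `positive`/`negative` (case-insensitive); anything else, `NA` included,
#'   becomes `"unknown"`.
#' @param source_name free-text name of the originating dataset.
#' @param source_tier `"tier1"` for authoritative sources whose labels are
#'   retained verbatim during merging (DILIrank/LiverTox/LTKB class), else
#'   `"tier2"`.
#' @return data.frame with columns `compound_id`, `smiles`, `canonical_key`
#'   (NA until standardization), `label`, `source_tier`, `source_name`,
#'   `status` (all start `"active"`), `reason`.
#' @export
compound_records <- function(compound_id, smiles, label,
                             source_name = "unknown", source_tier = "tier2") {
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id)) {
    dup <- unique(compound_id[duplicated(compound_id)])
    stop("duplicate compound_id: ", paste(dup, collapse = ", "))
  }
  n <- length(compound_id)
  if (length(smiles) == 1) smiles <- rep(smiles, n)
  stopifnot(length(smiles) == n)
  rec <- data.frame(
    compound_id = compound_id,
    smiles = as.character(smiles),
    canonical_key = rep(NA_character_, n),
    label = rep_len(normalize_label(label), n),
    source_tier = rep_len(as.character(source_tier), n),
    source_name = rep_len(as.character(source_name), n),
    status = rep("active", n),
    reason = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  bad_tier <- !rec$source_tier %in% TIERS
  if (any(bad_tier)) stop("source_tier must be one of: ", paste(TIERS, collapse = ", "))
  # structurally empty SMILES can never be standardized; flag at entry
  empty <- is.na(rec$smiles) | !nzchar(trimws(rec$smiles))
  rec$status[empty] <- "rejected_structure"
  rec$reason[empty] <- "empty SMILES"
  validate_records(rec)
}

normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "pos", "positive", "true")] <- "positive"
  out[x %in% c("0", "neg", "negative", "false")] <- "negative"
  out
}

validate_records <- function(rec) {
  miss <- setdiff(RECORD_COLUMNS, names(rec))
  if (length(miss)) stop("missing record columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(rec$compound_id)) {
    dup <- unique(rec$compound_id[duplicated(rec$compound_id)])
    stop("duplicate compound_id: ", paste(dup, collapse = ", "))
  }
  stopifnot(all(rec$label %in% LABELS), all(rec$status %in% STATUSES))
  rec[, c(RECORD_COLUMNS, setdiff(names(rec), RECORD_COLUMNS))]
}

#' Read a compound table from CSV, TSV or SDF
#'
#' CSV/TSV files need columns `compound_id`, `smiles`, `label`, `source_name`,
#' `source_tier` (extra columns `canonical_key`, `status`, `reason` are
#' honoured when present, so written datasets round-trip). SDF input takes the
#' identifier from the molecule title and label/provenance from `<LABEL>`,
#' `<SOURCE>`, `<SOURCE_TIER>` data fields; a missing `<LABEL>` tag yields
#' label `"unknown"`.
#'
#' Rows with an empty structure are kept with status `rejected_structure` and
#' a reason, never silently dropped.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"` or `"sdf"`; default guessed from the
#'   extension.
#' @return compound record data.frame (see [compound_records()]).
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "tsv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "sdf") return(read_sdf_records(path))
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  need <- c("compound_id", "smiles", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    return(compound_records(character(), character(), character()))
  }
  rec <- compound_records(
    tab$compound_id, tab$smiles, tab$label,
    source_name = if ("source_name" %in% names(tab)) tab$source_name else "unknown",
    source_tier = if ("source_tier" %in% names(tab)) tab$source_tier else "tier2"
  )
  # round-trip support: restore curation state saved by write_dataset()
  if ("status" %in% names(tab)) {
    st <- tab$status
    stopifnot(all(st %in% STATUSES))
    rec$status <- st
  }
  if ("canonical_key" %in% names(tab)) {
    ck <- tab$canonical_key
    ck[!nzchar(ck)] <- NA_character_
    rec$canonical_key <- ck
  }
  if ("reason" %in% names(tab)) {
    rs <- tab$reason
    rs[!nzchar(rs)] <- NA_character_
    rec$reason <- rs
  }
  if ("label" %in% names(tab)) rec$label <- normalize_label(tab$label)
  n_rej <- sum(rec$status == "rejected_structure")
  if (n_rej) message(n_rej, " record(s) carry status rejected_structure")
  validate_records(rec)
}

read_sdf_records <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  n <- length(sdf)
  ids <- character(n); smi <- character(n)
  lab <- character(n); src <- character(n); tier <- character(n)
  for (i in seq_len(n)) {
    mol <- sdf[[i]]
    ids[i] <- ChemmineR::header(mol)[["Molecule_Name"]]
    db <- ChemmineR::datablock(mol)
    lab[i] <- if ("LABEL" %in% names(db)) db[["LABEL"]] else NA_character_
    src[i] <- if ("SOURCE" %in% names(db)) db[["SOURCE"]] else "unknown"
    tier[i] <- if ("SOURCE_TIER" %in% names(db)) db[["SOURCE_TIER"]] else "tier2"
    smi[i] <- if ("SMILES" %in% names(db)) db[["SMILES"]] else
      as.character(ChemmineR::sdf2smiles(sdf[i]))
  }
  if (n == 0) return(compound_records(character(), character(), character()))
  compound_records(ids, smi, lab, source_name = src, source_tier = tier)
}

#' Write a compound dataset to disk
#'
#' CSV/TSV output preserves every record field exactly, so
#' `read_compound_table(write_dataset(x))` reproduces ids, labels, keys and
#' statuses. SDF output embeds `<LABEL>`, `<SOURCE>`, `<SOURCE_TIER>`,
#' `<SMILES>`, `<STATUS>` data fields and requires parsable structures.
#'
#' @param records compound record data.frame.
#' @param path output file.
#' @param format `"csv"`, `"tsv"` or `"sdf"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path, format = c("auto", "csv", "tsv", "sdf")) {
  format <- match.arg(format)
  records <- validate_records(records)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", tsv = "tsv", "csv")
  }
  if (format == "sdf") {
    write_sdf_records(records, path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    utils::write.table(records, path, sep = sep, row.names = FALSE,
                       quote = TRUE, na = "")
  }
  invisible(path)
}

write_sdf_records <- function(records, path) {
  ok <- records$status != "rejected_structure"
  if (!all(ok)) stop("SDF output cannot represent records with unparsable structures; ",
                     "use CSV/TSV for full round-trips")
  if (nrow(records) == 0) { file.create(path); return(invisible(path)) }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(records$smiles, records$compound_id))
  ChemmineR::datablock(sdf) <- lapply(seq_len(nrow(records)), function(i) c(
    LABEL = records$label[i],
    SOURCE = records$source_name[i],
    SOURCE_TIER = records$source_tier[i],
    SMILES = records$smiles[i],
    STATUS = records$status[i]
  ))
  ChemmineR::write.SDF(sdf, path, cid = TRUE)
  invisible(path)
}

#' Active (still-modelable) subset of a record table
#' @param records compound record data.frame.
#' @return records with `status == "active"`.
#' @export
active_records <- function(records) {
  records[records$status == "active", , drop = FALSE]
}
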