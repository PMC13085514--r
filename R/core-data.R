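# Data model and I/O: half-life tables, SMILES standardization, and the
# applicability-domain gate.

CENSOR_LEVELS <- c("exact", "left", "right")

#' Construct a half-life observation
#'
#' One reported soil DT50 value. Censored reports enter as bounds:
#' `"left"` means the study reported "< value" (half-life below the bound),
#' `"right"` means "> value" (half-life above the bound, typically "> last
#' sampling time point").
#'
#' @param value_days Positive DT50 in days.
#' @param censor One of `"exact"`, `"left"`, `"right"`.
#' @return A one-row `data.frame` with columns `value_days`, `censor`,
#'   `log_value` (log10 days).
#' @export
observation <- function(value_days, censor = "exact") {
  stopifnot(is.numeric(value_days), length(value_days) == length(censor) ||
              length(censor) == 1)
  censor <- rep_len(as.character(censor), length(value_days))
  if (!all(censor %in% CENSOR_LEVELS)) {
    stop("censor must be one of ", paste(CENSOR_LEVELS, collapse = ", "))
  }
  if (any(!is.finite(value_days)) || any(value_days <= 0)) {
    stop("value_days must be positive and finite")
  }
  data.frame(value_days = value_days, censor = censor,
             log_value = log10(value_days), stringsAsFactors = FALSE)
}

#' Construct a compound record
#'
#' @param compound_id Identifier string.
#' @param smiles Standardized (stereo-stripped, canonical) SMILES.
#' @param observations A `data.frame` as produced by [observation()]; may have
#'   zero rows for prediction-only compounds.
#' @param is_tp Is this a transformation product?
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(compound_id, smiles, observations = observation(numeric(0)),
                            is_tp = FALSE) {
  stopifnot(is.character(compound_id), length(compound_id) == 1,
            is.character(smiles), length(smiles) == 1,
            is.data.frame(observations))
  structure(list(compound_id = compound_id, smiles = smiles,
                 observations = observations, is_tp = isTRUE(is_tp)),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record %s: %s, %d observation(s)%s>\n", x$compound_id,
              x$smiles, nrow(x$observations), if (x$is_tp) ", TP" else ""))
  invisible(x)
}

#' Standardize a SMILES string
#'
#' Canonicalizes through RDKit with all stereochemical information removed
#' (stereospecific half-life prediction is out of scope; stereoisomers share
#' one record). Isotope labels are kept, so isotopomers remain distinct.
#' Idempotent: `standardize_structure(standardize_structure(s)) == standardize_structure(s)`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical stereo-free SMILES.
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles), all(nzchar(smiles)))
  res <- chem_batch("standardize", smiles)
  bad <- !vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (any(bad)) {
    stop("unparsable SMILES: ", paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  vapply(res, function(r) r$canonical, character(1))
}

#' Applicability-domain check
#'
#' The model's applicability domain covers single connected organic structures
#' of molecular weight below 1200 Da. Reasons reported (all that apply, not
#' short-circuited): `multi_fragment` (SMILES encodes several fragments, e.g.
#' salts and mixtures), `too_heavy` (MW >= 1200), `inorganic` (no carbon, or an
#' element outside H,B,C,N,O,F,Si,P,S,Cl,Br,I), `parse_failure`.
#'
#' @param smiles Character vector of SMILES.
#' @return A `data.frame` with columns `smiles`, `in_domain` (logical) and
#'   `reasons` (list column of character vectors; empty when in domain).
#' @export
check_applicability_domain <- function(smiles) {
  stopifnot(is.character(smiles))
  res <- chem_batch("profile", smiles)
  reasons <- lapply(res, function(r) {
    if (!isTRUE(r$ok)) return("parse_failure")
    out <- character(0)
    if (r$n_fragments > 1) out <- c(out, "multi_fragment")
    if (r$mw >= 1200) out <- c(out, "too_heavy")
    if (!isTRUE(r$has_carbon) || length(r$non_organic) > 0) out <- c(out, "inorganic")
    out
  })
  out <- data.frame(smiles = smiles,
                    in_domain = lengths(reasons) == 0,
                    stringsAsFactors = FALSE)
  out$reasons <- reasons
  out
}

.parse_censor_value <- function(value_raw, censor_raw) {
  # Accept both dialects: a dedicated censor column ("<", ">", "=", "exact",
  # "left", "right", empty) and a "<"/">" prefix embedded in the value field.
  value_raw <- trimws(as.character(value_raw))
  censor <- "exact"
  if (grepl("^<", value_raw)) {
    censor <- "left"; value_raw <- sub("^<", "", value_raw)
  } else if (grepl("^>", value_raw)) {
    censor <- "right"; value_raw <- sub("^>", "", value_raw)
  }
  cr <- trimws(as.character(censor_raw))
  if (!is.na(cr) && nzchar(cr)) {
    mapped <- switch(cr,
                     "<" = "left", "left" = "left",
                     ">" = "right", "right" = "right",
                     "=" = "exact", "exact" = "exact", NA_character_)
    if (is.na(mapped)) return(list(ok = FALSE, reason = paste0("unknown censor code '", cr, "'")))
    if (censor != "exact" && mapped != censor) {
      return(list(ok = FALSE, reason = "conflicting censor column and value prefix"))
    }
    if (censor == "exact") censor <- mapped
  }
  value <- suppressWarnings(as.numeric(value_raw))
  if (is.na(value) || !is.finite(value) || value <= 0) {
    return(list(ok = FALSE, reason = paste0("non-positive or non-numeric DT50 '", value_raw, "'")))
  }
  list(ok = TRUE, value = value, censor = censor)
}

#' Read a compound/half-life table
#'
#' Ingests a CSV/TSV shaped like a regulatory soil-study export: one row per
#' reported DT50, identified by compound id and SMILES. Rows are grouped into
#' one [compound_record()] per distinct standardized SMILES (so stereoisomer
#' entries merge); observation order within a compound follows input order.
#' Unusable rows (unparsable SMILES, bad values, unknown censor codes) are
#' collected in a rejects table attached as `attr(x, "rejects")`, never
#' silently dropped.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file, UTF-8, "." decimal.
#' @param column_map Named list mapping roles `compound_id`, `smiles`,
#'   `dt50_days`, `censor`, `is_tp` to column names. `censor` and `is_tp`
#'   columns are optional in the file.
#' @param rejects_path Optional path; if given, the rejects table is written
#'   there as CSV.
#' @return A list of `compound_record`, with attribute `rejects`.
#' @export
read_halflife_table <- function(path,
                                column_map = list(compound_id = "compound_id",
                                                  smiles = "smiles",
                                                  dt50_days = "dt50_days",
                                                  censor = "censor",
                                                  is_tp = "is_tp"),
                                rejects_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defaults <- list(compound_id = "compound_id", smiles = "smiles",
                   dt50_days = "dt50_days", censor = "censor", is_tp = "is_tp")
  column_map <- utils::modifyList(defaults, column_map)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  for (role in c("compound_id", "smiles", "dt50_days")) {
    if (!column_map[[role]] %in% names(df)) {
      stop("missing mandatory column '", column_map[[role]], "' (role ", role, ")",
           call. = FALSE)
    }
  }
  if (nrow(df) == 0) {
    warning("empty half-life table: ", path)
    out <- list()
    attr(out, "rejects") <- data.frame(row = integer(0), compound_id = character(0),
                                       smiles = character(0), reason = character(0),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  has_censor <- column_map$censor %in% names(df)
  has_tp <- column_map$is_tp %in% names(df)

  smiles_raw <- df[[column_map$smiles]]
  std <- chem_batch("standardize", smiles_raw)
  canon <- vapply(std, function(r) if (isTRUE(r$ok)) r$canonical else NA_character_,
                  character(1))

  rejects <- list()
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(canon[i])) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, compound_id = df[[column_map$compound_id]][i],
                   smiles = smiles_raw[i], reason = "unparsable SMILES",
                   stringsAsFactors = FALSE)
      next
    }
    pc <- .parse_censor_value(df[[column_map$dt50_days]][i],
                              if (has_censor) df[[column_map$censor]][i] else "")
    if (!pc$ok) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, compound_id = df[[column_map$compound_id]][i],
                   smiles = smiles_raw[i], reason = pc$reason,
                   stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(canon = canon[i],
                            compound_id = df[[column_map$compound_id]][i],
                            value = pc$value, censor = pc$censor,
                            is_tp = if (has_tp)
                              tolower(df[[column_map$is_tp]][i]) %in% c("true", "1", "yes")
                            else FALSE,
                            stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  records <- list()
  if (!is.null(rows) && nrow(rows) > 0) {
    for (cs in unique(rows$canon)) {
      sub <- rows[rows$canon == cs, , drop = FALSE]
      records[[length(records) + 1L]] <-
        compound_record(sub$compound_id[1], cs,
                        observation(sub$value, sub$censor),
                        is_tp = any(sub$is_tp))
    }
  }
  rej <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(row = integer(0), compound_id = character(0),
               smiles = character(0), reason = character(0), stringsAsFactors = FALSE)
  if (!is.null(rejects_path)) utils::write.csv(rej, rejects_path, row.names = FALSE)
  attr(records, "rejects") <- rej
  records
}

#' Write a compound/half-life table
#'
#' Inverse of [read_halflife_table()]: expands compound records back to one row
#' per observation, in the stored order. Censored observations are written with
#' a dedicated censor column (`<`, `>`, `=`).
#'
#' @param records List of `compound_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_halflife_table <- function(records, path) {
  rows <- lapply(records, function(rec) {
    obs <- rec$observations
    if (nrow(obs) == 0) return(NULL)
    data.frame(compound_id = rec$compound_id, smiles = rec$smiles,
               dt50_days = obs$value_days,
               censor = c(exact = "=", left = "<", right = ">")[obs$censor],
               is_tp = rec$is_tp, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
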