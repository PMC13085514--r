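# Molecular features: fingerprints and 2-D descriptors, min-max scaling,
# variance filtering and Spearman correlation-cluster reduction.

FEATURE_SETS <- c("maccs", "avalon", "path_fp_2048", "descriptors_2d", "external_table")

#' Feature set specification
#'
#' @param names Subset of `"maccs"` (166 structural keys), `"avalon"` (hashed
#'   substructure fingerprint, 512 bits), `"path_fp_2048"` (path-based
#'   fingerprint, 2048 bits), `"descriptors_2d"` (RDKit 2-D descriptor set),
#'   `"external_table"` (user-supplied precomputed descriptor CSV, e.g. from an
#'   external descriptor engine).
#' @param external_path CSV path for `"external_table"`: first column
#'   `compound_id`, remaining columns numeric descriptors.
#' @return An object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(names = "maccs", external_path = NULL) {
  names <- match.arg(names, FEATURE_SETS, several.ok = TRUE)
  if ("external_table" %in% names && is.null(external_path)) {
    stop("external_table requires external_path", call. = FALSE)
  }
  structure(list(names = names, external_path = external_path),
            class = "feature_set_spec")
}

feature_matrix <- function(values, compound_ids, source, scaler_state = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(compound_ids),
            ncol(values) == length(source))
  structure(list(values = values, compound_ids = compound_ids,
                 feature_names = colnames(values), source = source,
                 scaler_state = scaler_state),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %d compounds x %d features (%s)%s>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$source), collapse = ", "),
              if (is.null(x$scaler_state)) "" else ", scaled"))
  invisible(x)
}

.bits_to_matrix <- function(res, n_bits, prefix) {
  m <- matrix(0, length(res), n_bits)
  for (i in seq_along(res)) {
    on <- unlist(res[[i]]$on_bits)
    if (length(on)) m[i, on + 1L] <- 1
  }
  colnames(m) <- sprintf("%s_%04d", prefix, seq_len(n_bits))
  m
}

#' Compute a (raw, unscaled) feature matrix
#'
#' Deterministic per SMILES. Fingerprint blocks are 0/1; descriptor columns
#' are real-valued. Descriptor columns that cannot be computed for every
#' compound are dropped (with a message), so the result has no missing values.
#'
#' @param records List of `compound_record`, or a character vector of
#'   standardized SMILES (then ids default to the SMILES).
#' @param spec A [feature_set_spec()].
#' @return A `feature_matrix` (unscaled).
#' @export
featurize <- function(records, spec = feature_set_spec()) {
  stopifnot(inherits(spec, "feature_set_spec"))
  if (is.character(records)) {
    smiles <- records; ids <- records
  } else {
    smiles <- vapply(records, function(r) r$smiles, character(1))
    ids <- vapply(records, function(r) r$compound_id, character(1))
  }
  blocks <- list(); sources <- list()
  for (nm in spec$names) {
    block <- switch(nm,
      maccs = .bits_to_matrix(chem_batch("fingerprint", smiles,
                                         list(fp_type = "maccs", n_bits = 166)),
                              166, "maccs"),
      avalon = .bits_to_matrix(chem_batch("fingerprint", smiles,
                                          list(fp_type = "avalon", n_bits = 512)),
                               512, "avalon"),
      path_fp_2048 = .bits_to_matrix(chem_batch("fingerprint", smiles,
                                                list(fp_type = "rdk", n_bits = 2048)),
                                     2048, "path"),
      descriptors_2d = {
        res <- chem_batch("descriptors", smiles)
        dn <- names(res[[1]]$descriptors)
        m <- t(vapply(res, function(r) {
          vapply(dn, function(k) {
            v <- r$descriptors[[k]]
            if (is.null(v)) NA_real_ else as.numeric(v)
          }, numeric(1))
        }, numeric(length(dn))))
        colnames(m) <- paste0("desc2d_", dn)
        m
      },
      external_table = {
        ext <- utils::read.csv(spec$external_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
        idx <- match(ids, ext[[1]])
        if (anyNA(idx)) {
          stop("external_table is missing compounds: ",
               paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
        }
        m <- as.matrix(ext[idx, -1, drop = FALSE])
        storage.mode(m) <- "double"
        colnames(m) <- paste0("ext_", colnames(ext)[-1])
        m
      })
    blocks[[nm]] <- block
    sources[[nm]] <- rep(nm, ncol(block))
  }
  values <- do.call(cbind, blocks)
  source <- unlist(sources, use.names = FALSE)
  bad <- colSums(!is.finite(values)) > 0
  if (any(bad)) {
    message("dropping ", sum(bad), " feature(s) not computable for all compounds: ",
            paste(utils::head(colnames(values)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    values <- values[, !bad, drop = FALSE]
    source <- source[!bad]
  }
  feature_matrix(values, ids, source)
}

#' Fit / apply min-max scaling
#'
#' `fit_scale()` learns per-feature (min, max) on training compounds and maps
#' them to `[0, 1]`; constant features map to 0. `apply_scale()` transforms new
#' compounds with a previously fitted state; values outside the training range
#' are deliberately not clipped, so out-of-range queries land outside `[0, 1]`.
#'
#' @param fm A `feature_matrix`.
#' @return A scaled `feature_matrix` with `scaler_state` set.
#' @export
fit_scale <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  mins <- apply(fm$values, 2, min)
  maxs <- apply(fm$values, 2, max)
  state <- data.frame(feature = colnames(fm$values), min = mins, max = maxs,
                      stringsAsFactors = FALSE, row.names = NULL)
  out <- apply_scale(fm, state)
  out
}

#' @rdname fit_scale
#' @param scaler_state A `data.frame` (feature, min, max) from `fit_scale()`.
#' @export
apply_scale <- function(fm, scaler_state) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(scaler_state)) stop("scaler has not been fitted", call. = FALSE)
  idx <- match(colnames(fm$values), scaler_state$feature)
  if (anyNA(idx)) {
    stop("scaler state lacks features: ",
         paste(colnames(fm$values)[is.na(idx)][1:5], collapse = ", "), call. = FALSE)
  }
  mins <- scaler_state$min[idx]; maxs <- scaler_state$max[idx]
  range <- maxs - mins
  range[range == 0] <- 1  # constant columns map to 0
  scaled <- sweep(sweep(fm$values, 2, mins, "-"), 2, range, "/")
  feature_matrix(scaled, fm$compound_ids, fm$source, scaler_state = scaler_state)
}

#' Variance and correlation-cluster feature selection
#'
#' Two-stage reduction on a scaled training matrix: (1) drop features with
#' variance below `variance_threshold`; (2) cluster the rest by complete-
#' linkage hierarchical clustering on the distance `1 - |Spearman r|`, cut at
#' `1 - corr_cut` (default: clusters of features correlated at `|r| >= 0.99`),
#' and keep one representative per cluster -- the member with the highest
#' variance, ties broken by first column order.
#'
#' @param fm A scaled `feature_matrix` with at least 2 rows.
#' @param variance_threshold Minimum feature variance (default 0.02).
#' @param corr_cut Absolute Spearman correlation at or above which features are
#'   considered redundant (default 0.99).
#' @return A `feature_matrix` restricted to the selected features, with the
#'   full selection report in `attr(, "selection")` (columns `feature`,
#'   `source`, `variance`, `cluster_id`, `retained`).
#' @export
select_features <- function(fm, variance_threshold = 0.02, corr_cut = 0.99) {
  stopifnot(inherits(fm, "feature_matrix"), nrow(fm$values) >= 2)
  if (is.null(fm$scaler_state)) stop("select_features expects a scaled matrix",
                                     call. = FALSE)
  vars <- apply(fm$values, 2, stats::var)
  pass_var <- vars >= variance_threshold
  report <- data.frame(feature = colnames(fm$values), source = fm$source,
                       variance = vars, cluster_id = NA_integer_,
                       retained = FALSE, stringsAsFactors = FALSE,
                       row.names = NULL)
  keep_idx <- which(pass_var)
  if (length(keep_idx) == 0) {
    stop("no features survive the variance threshold (", variance_threshold,
         "); lower the threshold", call. = FALSE)
  }
  if (length(keep_idx) == 1) {
    cl <- 1L
  } else {
    r <- suppressWarnings(stats::cor(fm$values[, keep_idx, drop = FALSE],
                                     method = "spearman"))
    d <- 1 - abs(r)
    d[!is.finite(d)] <- 1  # unrelated under ties; keep both
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    cl <- stats::cutree(hc, h = 1 - corr_cut)
  }
  report$cluster_id[keep_idx] <- cl
  retained <- vapply(split(keep_idx, cl), function(members) {
    members[which.max(vars[members])]  # ties: which.max takes the first
  }, integer(1))
  retained <- sort(unname(retained))  # preserve column order
  report$retained[retained] <- TRUE
  out <- feature_matrix(fm$values[, retained, drop = FALSE], fm$compound_ids,
                        fm$source[retained], scaler_state = fm$scaler_state)
  attr(out, "selection") <- report
  out
}

.tanimoto <- function(a, b) {
  # a, b: sorted integer on-bit indices; two empty fingerprints -> 0
  if (length(a) == 0 && length(b) == 0) return(0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Mean k-nearest-neighbour Tanimoto distance to the training set
#'
#' For each query, computes Morgan fingerprints (radius 2, 2048 bits) and
#' returns `1 - mean(k largest Tanimoto similarities)` to the training
#' compounds; in `[0, 1]`, 0 when the query is a training compound (k = 1).
#' Used as the chemical-distance axis of distance-based calibration.
#'
#' @param query_smiles,train_smiles Character vectors of SMILES.
#' @param k Number of nearest training compounds (default 5; `k <= length(train_smiles)`).
#' @return Numeric vector of distances, one per query.
#' @export
tanimoto_knn_distance <- function(query_smiles, train_smiles, k = 5) {
  if (length(train_smiles) == 0) stop("empty training set", call. = FALSE)
  if (k > length(train_smiles)) stop("k exceeds the training-set size", call. = FALSE)
  opts <- list(fp_type = "morgan", n_bits = 2048)
  fq <- lapply(chem_batch("fingerprint", query_smiles, opts),
               function(r) sort(unlist(r$on_bits)))
  ft <- lapply(chem_batch("fingerprint", train_smiles, opts),
               function(r) sort(unlist(r$on_bits)))
  vapply(fq, function(q) {
    sims <- vapply(ft, function(t) .tanimoto(q, t), numeric(1))
    1 - mean(sort(sims, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
}
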