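#' Read long-format EHR observations
#'
#' Validated reader for the delimited long format (`patient_id`, `date`,
#' `item`, `value`). Dates parse as ISO-8601; rows with unparseable dates or
#' non-numeric values are skipped and counted; a missing required column or
#' an empty file is an error.
#'
#' @param path Path to a delimited text file with a header.
#' @return Typed tibble with a `skipped_rows` attribute.
#' @export
read_long_ehr <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) abort("empty observation file")
  need <- c("patient_id", "date", "item", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste("missing required column(s):", paste(miss, collapse = ", ")))
  d <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  v <- suppressWarnings(as.numeric(raw$value))
  bad <- is.na(d) | is.na(v)
  if (any(bad)) {
    warn(sprintf("skipping %d malformed row(s)", sum(bad)))
  }
  out <- tibble::tibble(patient_id = as.character(raw$patient_id)[!bad],
                        date = d[!bad], item = as.character(raw$item)[!bad],
                        value = v[!bad])
  attr(out, "skipped_rows") <- sum(bad)
  out
}

#' Read an item reference-range table
#'
#' @param path CSV with columns `item`, `lower`, `upper` (`lower < upper`).
#' @return Typed tibble.
#' @export
read_reference_ranges <- function(path) {
  rr <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("item", "lower", "upper") %in% names(rr))) {
    abort("reference ranges need columns item, lower, upper")
  }
  if (any(rr$lower >= rr$upper)) abort("reference ranges require lower < upper")
  rr
}

#' Read patient metadata
#'
#' @param path CSV with columns `patient_id`, `sex`, `death_flag`, optional
#'   semicolon-separated `drugs`.
#' @return Typed tibble (missing `drugs` filled with "").
#' @export
read_metadata <- function(path) {
  md <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("patient_id", "sex", "death_flag") %in% names(md))) {
    abort("metadata needs columns patient_id, sex, death_flag")
  }
  md$patient_id <- as.character(md$patient_id)
  if (!"drugs" %in% names(md)) md$drugs <- ""
  md$drugs[is.na(md$drugs)] <- ""
  md
}

#' Write / read an observation tensor as plain text
#'
#' The on-disk layout is one long TSV (`patient_id`, `t`, `feature`,
#' `value`, `observed`, `imputed_value`) plus a JSON sidecar carrying the
#' feature table, frozen min-max statistics, kept items, metadata and the
#' missingness report.
#'
#' @param tensor An `ehr_tensor`.
#' @param dir Output directory.
#' @return `dir` invisibly (`write_tensor`); an `ehr_tensor` (`read_tensor`).
#' @export
write_tensor <- function(tensor, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- purrr::map_dfr(seq_along(tensor$x), function(i) {
    x <- tensor$x[[i]]
    tibble::tibble(
      patient_id = tensor$patient_id[i],
      t = rep(seq_len(nrow(x)), ncol(x)),
      feature = rep(colnames(x), each = nrow(x)),
      value = as.vector(x),
      observed = as.integer(as.vector(tensor$mask[[i]])),
      imputed_value = as.vector(tensor$x_imp[[i]])
    )
  })
  utils::write.table(long, file.path(dir, "tensor.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(features = tensor$features, stats = tensor$stats,
               items = tensor$items, meta = tensor$meta,
               report = tensor$report)
  jsonlite::write_json(side, file.path(dir, "tensor.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  long <- tibble::as_tibble(utils::read.delim(file.path(dir, "tensor.tsv")))
  side <- jsonlite::read_json(file.path(dir, "tensor.json"), simplifyVector = TRUE)
  feats <- side$features$feature
  per <- split(long, long$patient_id)
  pids <- unique(long$patient_id)
  mk <- function(df, col) {
    Tb <- max(df$t)
    m <- matrix(NA_real_, Tb, length(feats), dimnames = list(NULL, feats))
    m[cbind(df$t, match(df$feature, feats))] <- df[[col]]
    m
  }
  x <- lapply(pids, function(p) mk(per[[p]], "value"))
  xi <- lapply(pids, function(p) mk(per[[p]], "imputed_value"))
  mask <- lapply(pids, function(p) mk(per[[p]], "observed") == 1)
  names(x) <- names(xi) <- names(mask) <- pids
  structure(list(
    x = x, x_imp = xi, mask = mask,
    lengths = vapply(x, nrow, integer(1)), patient_id = pids,
    features = tibble::as_tibble(side$features),
    stats = tibble::as_tibble(side$stats),
    items = if (is.null(side$items)) NULL else tibble::as_tibble(side$items),
    meta = tibble::as_tibble(side$meta),
    report = side$report, config = NULL
  ), class = "ehr_tensor")
}

#' Save / load fitted state-space parameters
#'
#' Checkpoints are plain JSON: a format-version field, the architecture
#' dimensions and flavor, the training trace, and every weight matrix.
#'
#' @param fit A `dssm_fit`.
#' @param path Output file.
#' @return `path` invisibly (`write_dssm`); a `dssm_fit` (`read_dssm`).
#' @export
write_dssm <- function(fit, path) {
  obj <- list(
    format_version = 1L,
    flavor = fit$flavor, dims = fit$dims, seed = fit$seed,
    n_patients = fit$n_patients,
    features = fit$features,
    trace = fit$trace,
    params = lapply(fit$params, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
      else list(dim = NULL, data = as.vector(w))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dssm
#' @export
read_dssm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(w) {
    if (!is.null(w$dim)) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  attr(params, "dims") <- as.list(obj$dims)
  attr(params, "flavor") <- obj$flavor
  structure(list(
    params = params,
    trace = tibble::as_tibble(obj$trace),
    dims = as.list(obj$dims), flavor = obj$flavor,
    features = tibble::as_tibble(obj$features),
    seed = obj$seed, n_patients = obj$n_patients
  ), class = "dssm_fit")
}

write_latents <- function(latents, path, kind = "dssm") {
  con <- file(path, "w")
  writeLines(sprintf("# kind: %s", kind), con)
  utils::write.table(latents, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

read_latents <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
}
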