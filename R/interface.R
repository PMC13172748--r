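# High-level runners behind the command-line interface. Each takes plain
# paths/values, drives the geometry/EV/DVH modules, and writes JSON (and
# optionally CSV) reports. Coefficients are reported to 3 decimals and dose
# percentages to 1 decimal; full precision is kept internally.

#' Read an EV run configuration from a YAML file
#'
#' Recognised keys (all optional): `d_r`, `n`, `band_width`, `mode`,
#' `cap_weights`, `thresholds`, plus any of the `run_compare()` /
#' `run_dvh()` path arguments. Values given directly to the runners
#' override the file; the file overrides the defaults (`d_r = 1` cm,
#' `n = 1`, `band_width = 0.3` cm, banded mode).
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must be a YAML mapping", call. = FALSE)
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; give it back its
  # intended name (the distance-penalty exponent)
  names(cfg)[names(cfg) %in% c("FALSE", "false")] <- "n"
  cfg
}

ev_params_from_config <- function(config = list(), ...) {
  override <- list(...)
  override <- override[!vapply(override, is.null, logical(1))]
  merged <- utils::modifyList(config, override)
  keep <- intersect(names(merged),
                    c("d_r", "n", "band_width", "mode", "cap_weights"))
  do.call(ev_params, merged[keep])
}

round_report <- function(x, coef_digits = 3) {
  num <- c("JC", "DSC", "JC_EV", "DSC_EV")
  for (f in num) if (!is.null(x[[f]])) x[[f]] <- round(x[[f]], coef_digits)
  x
}

#' Compare one or many structure-mask pairs
#'
#' Computes the full [concordance()] result for a standard/reference mask
#' pair, or for every row of a manifest CSV with columns
#' `case,std_path,ref_path` (relative paths resolved against the manifest's
#' directory). Writes a JSON report mirroring the result fields (numbers at
#' full precision, plus a `rounded` block at table precision) and, for
#' cohorts, optionally a CSV with one row per case.
#'
#' @param std_path,ref_path paths to two mask volumes (NIfTI/NRRD) on the
#'   identical grid. Supply either these or `manifest`.
#' @param manifest path to a manifest CSV for a cohort run.
#' @param params an [ev_params()]; if `NULL`, built from `config` and the
#'   `d_r`/`n`/`band_width`/`mode` arguments.
#' @param config optional list from [read_run_config()].
#' @param d_r,n,band_width,mode optional single-parameter overrides.
#' @param report_json,report_csv output paths (optional).
#' @param verbose print per-case results.
#' @return A single `concordance_result`, or for a manifest a list with
#'   `cases` (data frame, one row per pair) and `results`.
#' @export
run_compare <- function(std_path = NULL, ref_path = NULL, manifest = NULL,
                        params = NULL, config = list(),
                        d_r = NULL, n = NULL, band_width = NULL, mode = NULL,
                        report_json = NULL, report_csv = NULL,
                        verbose = FALSE) {
  if (is.null(params))
    params <- ev_params_from_config(config, d_r = d_r, n = n,
                                    band_width = band_width, mode = mode)
  single <- !is.null(std_path) || !is.null(ref_path)
  if (single == !is.null(manifest))
    stop("supply either std_path/ref_path or a manifest, not both",
         call. = FALSE)

  if (single) {
    if (is.null(std_path) || is.null(ref_path))
      stop("both `std_path` and `ref_path` are required", call. = FALSE)
    res <- concordance(read_mask(std_path), read_mask(ref_path), params)
    if (verbose) print(res)
    if (!is.null(report_json)) write_concordance_json(res, report_json)
    if (!is.null(report_csv))
      utils::write.csv(cbind(case = basename(std_path), as.data.frame(res)),
                       report_csv, row.names = FALSE)
    return(invisible(res))
  }

  man <- utils::read.csv(manifest)
  need <- c("case", "std_path", "ref_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns case, std_path, ref_path", call. = FALSE)
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  results <- lapply(seq_len(nrow(man)), function(i) {
    concordance(read_mask(resolve(man$std_path[i])),
                read_mask(resolve(man$ref_path[i])), params)
  })
  cases <- do.call(rbind, lapply(results, as.data.frame))
  cases <- cbind(case = man$case, cases)
  if (verbose) print(cases)
  if (!is.null(report_csv))
    utils::write.csv(cases, report_csv, row.names = FALSE)
  if (!is.null(report_json))
    jsonlite::write_json(
      list(params = unclass(params),
           cases = cases,
           mean_JC = mean(cases$JC), mean_DSC = mean(cases$DSC),
           mean_JC_EV = mean(cases$JC_EV), mean_DSC_EV = mean(cases$DSC_EV)),
      report_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cases = cases, results = results))
}

write_concordance_json <- function(res, path) {
  fields <- c("V_Std", "V_Ref", "V_I", "V_Std_minus_I", "V_Ref_minus_I",
              "EV_Std_minus_I", "EV_Ref_minus_I", "EV_Std", "EV_Ref",
              "JC", "DSC", "JC_EV", "DSC_EV",
              "JC_EV_threshold", "DSC_EV_threshold",
              "concordant_JC_EV", "concordant_DSC_EV",
              "size_mismatch_caveat")
  out <- res[fields]
  out$rounded <- list(JC = round(res$JC, 3), DSC = round(res$DSC, 3),
                      JC_EV = round(res$JC_EV, 3),
                      DSC_EV = round(res$DSC_EV, 3))
  out$params <- unclass(res$params)
  out$bands <- list(std_minus_I = res$decomposition_std$bands,
                    ref_minus_I = res$decomposition_ref$bands)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Fit dose gradients for a directory of DVH exports
#'
#' Reads every `*.csv` DVH in a directory (header `dose_pct,volume_cc`),
#' fits the linear dose-gradient model per case, and summarises the cohort:
#' mean model, CV of the slope, and — when a `case,ptv_volume_cc` table is
#' supplied — the Pearson correlation of slope with PTV volume. The mean
#' model is evaluated at 0.2–1.0 cm in 0.2 cm steps, the dose levels
#' conventionally quoted for the linear penalty.
#'
#' @param dvh_dir directory of per-case DVH CSVs.
#' @param ptv_csv optional CSV `case,ptv_volume_cc`, where `case` matches
#'   the DVH file names without extension.
#' @param fit_range,step passed to [fit_gradient()].
#' @param report_json optional output path.
#' @param verbose print the cohort summary and PCT table.
#' @return A list with `fits` (named list of `gradient_fit`), `summary`
#'   (a [summarize_cohort()] result), and `pct_table` (data frame
#'   `d_cm`, `pct`, the mean model evaluated and rounded to 1 decimal).
#' @export
run_dvh <- function(dvh_dir, ptv_csv = NULL, fit_range = c(48, 100),
                    step = 2, report_json = NULL, verbose = FALSE) {
  if (!dir.exists(dvh_dir))
    stop("DVH directory not found: ", dvh_dir, call. = FALSE)
  files <- sort(list.files(dvh_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!is.null(ptv_csv)) files <- setdiff(files, normalizePath(ptv_csv,
                                                               mustWork = FALSE))
  if (length(files) == 0L)
    stop("no DVH CSV files in ", dvh_dir, call. = FALSE)
  fits <- lapply(files, function(f) fit_gradient(read_dvh(f), fit_range, step))
  names(fits) <- tools::file_path_sans_ext(basename(files))

  ptv <- NULL
  if (!is.null(ptv_csv)) {
    tab <- utils::read.csv(ptv_csv)
    if (!all(c("case", "ptv_volume_cc") %in% names(tab)))
      stop("PTV table must have columns case, ptv_volume_cc", call. = FALSE)
    idx <- match(names(fits), as.character(tab$case))
    if (anyNA(idx))
      stop("PTV table is missing cases: ",
           paste(names(fits)[is.na(idx)], collapse = ", "), call. = FALSE)
    ptv <- tab$ptv_volume_cc[idx]
  }
  summ <- summarize_cohort(fits, ptv)
  d <- seq(0.2, 1.0, by = 0.2)
  pct_table <- data.frame(
    d_cm = d, pct = round(evaluate_model(summ$mean_B0, summ$mean_B1, d), 1))
  if (verbose) {
    print(summ)
    print(pct_table, row.names = FALSE)
  }
  if (!is.null(report_json)) {
    per_case <- lapply(fits, function(f)
      list(B0 = f$B0, B1 = f$B1, se_B0 = f$se_B0, se_B1 = f$se_B1, R2 = f$R2))
    jsonlite::write_json(
      list(cases = per_case, summary = unclass(summ),
           mean_model_pct = pct_table),
      report_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(fits = fits, summary = summ, pct_table = pct_table))
}

#' Generate phantom files
#'
#' Writes a sphere-pair mask phantom (NIfTI or NRRD) and/or a synthetic DVH
#' CSV, deterministically for a given configuration. The phantom spec is a
#' list (typically from [read_run_config()]) with an element `sphere_pair`
#' (fields `r0`, and either `margin` for the concentric pair or `r_ref` +
#' `offset` for the displaced one; optional `spacing`) and/or `dvh` (fields
#' of [dvh_generator_spec()]).
#'
#' @param spec configuration list.
#' @param out_dir output directory, created if needed.
#' @param format mask file format, `"nii.gz"`, `"nii"`, or `"nrrd"`.
#' @return Named character vector of the files written, invisibly.
#' @export
run_phantom <- function(spec, out_dir = ".", format = "nii.gz") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  if (!is.null(spec$sphere_pair)) {
    sp <- spec$sphere_pair
    spacing <- sp$spacing %||% 0.1
    pair <- if (!is.null(sp$offset)) {
      make_sphere_pair_displaced(r0 = sp$r0, r_ref = sp$r_ref,
                                 offset = unlist(sp$offset),
                                 spacing = spacing)
    } else {
      make_sphere_pair_uniform(r0 = sp$r0, margin = sp$margin %||% 0.6,
                               spacing = spacing)
    }
    std_file <- file.path(out_dir, paste0("phantom_std.", format))
    ref_file <- file.path(out_dir, paste0("phantom_ref.", format))
    write_mask(pair$std, std_file)
    write_mask(pair$ref, ref_file)
    written <- c(written, std = std_file, ref = ref_file)
  }
  if (!is.null(spec$dvh)) {
    gs <- do.call(dvh_generator_spec, spec$dvh)
    dvh_file <- file.path(out_dir, "phantom_dvh.csv")
    write_dvh(synthesize_dvh(gs), dvh_file)
    written <- c(written, dvh = dvh_file)
  }
  if (length(written) == 0L)
    stop("phantom spec has neither `sphere_pair` nor `dvh`", call. = FALSE)
  invisible(written)
}
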