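# the 6 x 6 experiment grid: input-mix strategies

radiomics_subcats <- c("CT", "SPECT", "CT+Clinical", "SPECT+Clinical",
                       "CT+SPECT", "CT+SPECT+Clinical")
dose_subcats <- c("Dose", "BED", "Dose+BED", "Dose+Clinical",
                  "BED+Clinical", "BED+Dose+Clinical")

#' Enumerate the 36 modeling strategies
#'
#' Six categories (MAA/Y90 x radiomics/dosiomics/DVH) times six input-mix
#' subcategories: radiomics mixes CT, SPECT and clinical features;
#' dosiomics and DVH mix physical dose, BED and clinical features. Clinical
#' subcategories use the 14 retained covariates (sex and extrahepatic
#' metastasis are excluded for extreme class imbalance).
#'
#' @param available Character vector of available table names (e.g.
#'   `c("CT", "SPECT_MAA", ..., "DVC", "CLINICAL")`). Strategies whose
#'   inputs are not all present are flagged unsatisfiable but still
#'   enumerated.
#' @return Tibble with `category`, `subcategory`, `inputs` (list column of
#'   required table names) and `satisfiable`.
#' @export
build_strategies <- function(available = c("CT", "SPECT_MAA", "SPECT_Y90",
                                           "DOSE_MAA", "DOSE_Y90",
                                           "BED_MAA", "BED_Y90",
                                           "DVC", "CLINICAL")) {
  rows <- list()
  add <- function(category, subcategory, inputs) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      category = category, subcategory = subcategory,
      inputs = list(inputs))
  }
  for (nuc in c("MAA", "Y90")) {
    spect <- paste0("SPECT_", nuc)
    for (sub in radiomics_subcats) {
      parts <- strsplit(sub, "+", fixed = TRUE)[[1]]
      inp <- character(0)
      if ("CT" %in% parts) inp <- c(inp, "CT")
      if ("SPECT" %in% parts) inp <- c(inp, spect)
      if ("Clinical" %in% parts) inp <- c(inp, "CLINICAL")
      add(paste0(nuc, "-radiomics"), sub, inp)
    }
    for (sub in dose_subcats) {
      parts <- strsplit(sub, "+", fixed = TRUE)[[1]]
      inp <- character(0)
      if ("Dose" %in% parts) inp <- c(inp, paste0("DOSE_", nuc))
      if ("BED" %in% parts) inp <- c(inp, paste0("BED_", nuc))
      if ("Clinical" %in% parts) inp <- c(inp, "CLINICAL")
      add(paste0(nuc, "-dosiomics"), sub, inp)
    }
    for (sub in dose_subcats) {
      parts <- strsplit(sub, "+", fixed = TRUE)[[1]]
      inp <- "DVC"
      if ("Clinical" %in% parts) inp <- c(inp, "CLINICAL")
      add(paste0(nuc, "-DVH"), sub, inp)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$satisfiable <- vapply(out$inputs, function(i) all(i %in% available),
                            logical(1))
  out
}

clinical_feature_matrix <- function(clinical) {
  excl <- attr(clinical, "excluded") %||% c("sex", "extrahepatic_metastasis")
  keep <- setdiff(names(clinical), c("case_id", "label", excl))
  num <- clinical[keep]
  num <- num[vapply(num, is.numeric, logical(1))]
  names(num) <- paste0("clin__", names(num))
  dplyr::bind_cols(clinical["case_id"], num)
}

dvc_strategy_columns <- function(dvc, nuclide, parts) {
  cols <- character(0)
  if ("Dose" %in% parts) {
    cols <- c(cols, grep(paste0("_", nuclide, "_dose"), names(dvc),
                         value = TRUE))
  }
  if ("BED" %in% parts) {
    cols <- c(cols, grep(paste0("_", nuclide, "_bed"), names(dvc),
                         value = TRUE))
  }
  c(cols, intersect(c("LSF", "injected_activity_GBq"), names(dvc)))
}

#' Assemble the modeling table of one strategy
#'
#' Joins the strategy's input tables by `case_id` into one cases-by-features
#' tibble with `case_id`, `label` and channel-prefixed feature columns.
#'
#' @param category,subcategory A row of [build_strategies()].
#' @param tables Named list of feature tables (channels, `DVC`, `CLINICAL`).
#' @return Tibble ready for [nested_cv_evaluate()].
#' @export
assemble_strategy_table <- function(category, subcategory, tables) {
  nuc <- sub("-.*$", "", category)
  kind <- sub("^[^-]+-", "", category)
  parts <- strsplit(subcategory, "+", fixed = TRUE)[[1]]
  pieces <- list()
  grab <- function(name) {
    tb <- tables[[name]]
    if (is.null(tb)) stop("missing table: ", name, call. = FALSE)
    feats <- tb[setdiff(names(tb), c("case_id", "label"))]
    feats <- feats[vapply(feats, is.numeric, logical(1))]
    names(feats) <- paste0(tolower(name), "__", names(feats))
    dplyr::bind_cols(tb["case_id"], feats)
  }
  if (kind == "radiomics") {
    if ("CT" %in% parts) pieces <- c(pieces, list(grab("CT")))
    if ("SPECT" %in% parts) pieces <- c(pieces,
                                        list(grab(paste0("SPECT_", nuc))))
  } else if (kind == "dosiomics") {
    if ("Dose" %in% parts) pieces <- c(pieces,
                                       list(grab(paste0("DOSE_", nuc))))
    if ("BED" %in% parts) pieces <- c(pieces,
                                      list(grab(paste0("BED_", nuc))))
  } else if (kind == "DVH") {
    dvc <- tables$DVC
    if (is.null(dvc)) stop("missing table: DVC", call. = FALSE)
    cols <- dvc_strategy_columns(dvc, nuc, parts)
    pieces <- c(pieces, list(dvc[c("case_id", cols)]))
  } else {
    stop("unknown category kind: ", kind, call. = FALSE)
  }
  if ("Clinical" %in% parts) {
    pieces <- c(pieces, list(clinical_feature_matrix(tables$CLINICAL)))
  }
  out <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "case_id"),
                pieces)
  # labels from whichever input table carries them
  lab <- NULL
  for (tb in tables) {
    if (!is.null(tb) && all(c("case_id", "label") %in% names(tb))) {
      lab <- tb[c("case_id", "label")]
      break
    }
  }
  dplyr::inner_join(lab, out, by = "case_id")
}
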