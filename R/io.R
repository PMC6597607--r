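## Dataset and configuration I/O. Datasets use the de facto pharmacometric
## long format: columns ID, TIME, AMT, EVID (1 dose / 0 observation), SS
## (1 with II for steady-state doses), II, DV (mg/L), MDV, WT, AGE, SEX
## (0 male / 1 female). Run configurations are YAML with full validation.

#' Read a PK dataset
#'
#' Reads a NONMEM-style CSV into a [PKStudy]. `SS`, `II` and `MDV` default
#' to 0 when absent. Observation rows without a recorded sampling time are
#' excluded with a message reporting the count.
#'
#' @param path CSV file path.
#' @return a [PKStudy].
#' @export
readDataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(d) == 0) stop("empty dataset: ", path)
  for (col in c("SS", "II", "MDV")) if (is.null(d[[col]])) d[[col]] <- 0
  miss <- setdiff(REQUIRED_COLUMNS, names(d))
  if (length(miss) > 0)
    stop("dataset is missing columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(REQUIRED_COLUMNS, c("ID", "DV"))) {
    if (!is.numeric(d[[col]]))
      stop("non-numeric values in column ", col)
  }
  noTime <- d$EVID == 0 & is.na(d$TIME)
  if (any(noTime)) {
    message(sum(noTime), " observation row(s) without a recorded sampling ",
            "time excluded")
    d <- d[!noTime, , drop = FALSE]
  }
  if (any(is.na(d$TIME))) stop("dose rows must carry a time")
  key <- paste(d$ID, d$TIME, d$EVID)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1]
    stop("duplicate (ID, TIME, EVID) record at row ", row)
  }
  PKStudy(d[, REQUIRED_COLUMNS])
}

#' Write a PK dataset
#'
#' Inverse of [readDataset()]; optionally writes the generating parameters
#' of a simulated study to a YAML sidecar.
#'
#' @param study a [PKStudy].
#' @param path output CSV path.
#' @param truthPath optional path for the truth sidecar YAML.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(study, path, truthPath = NULL) {
  write.csv(study@data, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(truthPath) && length(study@truth) > 0)
    yaml::write_yaml(study@truth, truthPath)
  invisible(path)
}

#' Read a drug-property table
#'
#' CSV with columns `name`, `extraction_ratio`, `fu`, `binding_protein`,
#' `f_cyp3a`.
#'
#' @param path CSV file path.
#' @return a list of [DrugProperties], named by drug.
#' @export
readDrugProperties <- function(path) {
  d <- read.csv(path)
  need <- c("name", "extraction_ratio", "fu", "binding_protein", "f_cyp3a")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("drug-property table is missing columns: ",
         paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(d)), function(i)
    DrugProperties(d$name[i], d$extraction_ratio[i], d$fu[i],
                   d$binding_protein[i], d$f_cyp3a[i]))
  names(out) <- d$name
  out
}

## recognized configuration schema: NULL marks a subtree
.CONFIG_SCHEMA <- list(
  dataset = NULL,
  model = list(compartments = NULL, ka = NULL, dosing = NULL, iiv = NULL,
               error_model = NULL),
  estimation = list(method = NULL, rel_tol = NULL, seed = NULL),
  evaluation = list(bootstrap_n = NULL, npde_n = NULL),
  scaling = list(cl_ref = NULL, wt_ref = NULL, exponent = NULL))

#' Read and validate a run configuration
#'
#' YAML configuration for the command-line pipeline. Unknown keys are
#' errors. Defaults: estimation method `"focei"` with seed 1; bootstrap
#' 250 resamples; NPDE 1000 simulations; scaling reference 70 kg with
#' exponent 0.874; model ka 3.5 1/h (single dosing) or 1 1/h
#' (steady-state).
#'
#' @param path YAML file path.
#' @return a validated named list of settings.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  .checkKeys(cfg, .CONFIG_SCHEMA, "")
  dosing <- cfg$model$dosing %||% "single"
  model <- list(
    compartments = cfg$model$compartments %||% 2,
    ka = cfg$model$ka %||% (if (dosing == "single") 3.5 else 1.0),
    dosing = dosing,
    iiv = cfg$model$iiv %||% c("cl", "vc"),
    error_model = cfg$model$error_model %||% "proportional")
  list(dataset = cfg$dataset,
       model = model,
       estimation = list(method = cfg$estimation$method %||% "focei",
                         rel_tol = cfg$estimation$rel_tol %||% 1e-6,
                         seed = cfg$estimation$seed %||% 1),
       evaluation = list(bootstrap_n = cfg$evaluation$bootstrap_n %||% 250,
                         npde_n = cfg$evaluation$npde_n %||% 1000),
       scaling = list(cl_ref = cfg$scaling$cl_ref,
                      wt_ref = cfg$scaling$wt_ref %||% 70,
                      exponent = cfg$scaling$exponent %||% 0.874))
}

.checkKeys <- function(x, schema, where) {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown) > 0)
    stop("unknown configuration key", if (length(unknown) > 1) "s", ": ",
         paste0(where, unknown, collapse = ", "))
  for (nm in names(x)) {
    if (is.list(schema[[nm]]) && !is.null(x[[nm]])) {
      if (!is.list(x[[nm]]))
        stop("configuration key '", where, nm, "' must be a mapping")
      .checkKeys(x[[nm]], schema[[nm]], paste0(where, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Reference minimum-age classes for selected CYP3A substrates
#'
#' The reporting lookup of per-drug minimum ages down to which clearance
#' scaling with the pediatric midazolam covariate function is expected to
#' be accurate, shipped as a package data file.
#'
#' @return `data.frame` with columns `name` and `min_age_class`.
#' @export
cyp3aMinAgeReference <- function() {
  read.csv(system.file("extdata", "cyp3a_min_age_reference.csv",
                       package = "pedpk"))
}
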