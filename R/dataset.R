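#' Competing-risks dataset
#'
#' Bundles the subject-level survival information with a subjects x features
#' expression matrix. One row per subject: observed time \eqn{T_i} (months),
#' event indicator \eqn{\Delta_i} (1 = event observed, 0 = censored), event
#' type \eqn{\epsilon_i \in \{1, 2\}} (1 = death after a cardiovascular event,
#' 2 = death without a prior cardiovascular event; meaningful only when an
#' event was observed), and clinical covariates (at minimum `age` in years and
#' the binary `prior_cv`).
#'
#' @param subjects data frame with columns `id`, `time`, `status`, `cause`,
#'   `age`, `prior_cv` (and possibly further clinical covariates). `cause`
#'   must be `NA` for censored subjects and 1 or 2 for events.
#' @param expression numeric matrix, one row per subject in the same order as
#'   `subjects`, with unique column names.
#' @param endpoint_version `"original"` or `"updated"`.
#' @return a validated object of class `crs_dataset`.
#' @export
competing_risks_dataset <- function(subjects, expression,
                                    endpoint_version = c("original", "updated")) {
  endpoint_version <- match.arg(endpoint_version)
  subjects <- as.data.frame(subjects)
  required <- c("id", "time", "status", "cause", "age", "prior_cv")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols)) {
    stop("survival table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"

  n <- nrow(subjects)
  if (n == 0L) stop("empty dataset refused")
  if (nrow(expression) != n) {
    stop(sprintf("expression has %d rows but the survival table has %d subjects",
                 nrow(expression), n))
  }
  if (anyDuplicated(subjects$id)) stop("subject ids must be unique")
  fn <- colnames(expression)
  if (is.null(fn) || anyDuplicated(fn)) stop("feature names must be present and unique")

  bad <- which(!is.finite(subjects$time) | subjects$time < 0)
  if (length(bad)) stop("negative or non-finite observed_time in row(s): ",
                        paste(head(bad, 10L), collapse = ", "))
  bad <- which(!subjects$status %in% c(0, 1))
  if (length(bad)) stop("event indicator must be 0/1; offending row(s): ",
                        paste(head(bad, 10L), collapse = ", "))
  ev <- subjects$status == 1
  bad <- which(ev & !subjects$cause %in% c(1, 2))
  if (length(bad)) stop("unknown event type code for event row(s): ",
                        paste(head(bad, 10L), collapse = ", "))
  bad <- which(!ev & !is.na(subjects$cause))
  if (length(bad)) stop("event_type present for censored row(s): ",
                        paste(head(bad, 10L), collapse = ", "))
  clin <- subjects[, setdiff(names(subjects), c("id", "cause")), drop = FALSE]
  if (anyNA(clin)) stop("missing values in the survival table are rejected, not imputed")
  if (anyNA(expression)) stop("missing values in the expression matrix are rejected")

  rownames(expression) <- as.character(subjects$id)
  structure(list(subjects = subjects, expression = expression,
                 endpoint_version = endpoint_version),
            class = "crs_dataset")
}

#' @export
print.crs_dataset <- function(x, ...) {
  n <- nrow(x$subjects)
  ev <- x$subjects$status == 1
  cat(sprintf("competing-risks dataset: %d subjects, %d features (%s endpoint)\n",
              n, ncol(x$expression), x$endpoint_version))
  cat(sprintf("  events: %d cause 1, %d cause 2; %d censored\n",
              sum(ev & x$subjects$cause == 1, na.rm = TRUE),
              sum(ev & x$subjects$cause == 2, na.rm = TRUE), sum(!ev)))
  invisible(x)
}

#' Number of subjects / event counts
#' @param dataset a `crs_dataset`.
#' @param cause event type (1 or 2).
#' @return integer count.
#' @export
n_events <- function(dataset, cause) {
  sum(dataset$subjects$status == 1 & dataset$subjects$cause == cause, na.rm = TRUE)
}

#' Read a competing-risks dataset from delimited text
#'
#' The survival table is a CSV with header columns
#' `id,time,status,cause,age,prior_cv,...`; the expression matrix a TSV whose
#' first column is the subject id and remaining columns are features. Subjects
#' are aligned by id; the survival-table order is canonical.
#'
#' @param survival_path path to the survival CSV.
#' @param expression_path path to the expression TSV.
#' @param endpoint endpoint version tag to record.
#' @return a `crs_dataset`.
#' @export
read_dataset <- function(survival_path, expression_path,
                         endpoint = c("original", "updated")) {
  endpoint <- match.arg(endpoint)
  if (!file.exists(survival_path)) stop("survival file not found: ", survival_path)
  if (!file.exists(expression_path)) stop("expression file not found: ", expression_path)
  subjects <- read.csv(survival_path, stringsAsFactors = FALSE)
  subjects$cause[subjects$status == 0] <- NA
  expr_df <- read.delim(expression_path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(expr_df[[1L]])
  expr <- as.matrix(expr_df[, -1L, drop = FALSE])
  missing_ids <- setdiff(as.character(subjects$id), ids)
  if (length(missing_ids)) {
    stop("expression file is missing subject id(s): ",
         paste(head(missing_ids, 10L), collapse = ", "))
  }
  expr <- expr[match(as.character(subjects$id), ids), , drop = FALSE]
  competing_risks_dataset(subjects, expr, endpoint)
}

#' Write a competing-risks dataset to delimited text
#'
#' Inverse of [read_dataset()]: round-trips up to float formatting tolerance.
#'
#' @param dataset a `crs_dataset`.
#' @param survival_path,expression_path output paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(dataset, survival_path, expression_path) {
  write.csv(dataset$subjects, survival_path, row.names = FALSE, na = "")
  expr_df <- data.frame(id = dataset$subjects$id, dataset$expression,
                        check.names = FALSE)
  write.table(expr_df, expression_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(survival_path, expression_path))
}

# canonical 3-level endpoint label per subject
endpoint_label <- function(subjects) {
  ifelse(subjects$status == 0, "none",
         ifelse(subjects$cause == 1, "cause1", "cause2"))
}

#' Apply an endpoint update (relabeling) to a dataset
#'
#' Cohorts with ongoing follow-up may revise event classifications; the
#' relabeling maps every subject's original endpoint label (`"none"`,
#' `"cause1"`, `"cause2"`) to an updated one. Observed times are unchanged and
#' the returned dataset is tagged `endpoint_version = "updated"`.
#'
#' @param dataset a `crs_dataset`.
#' @param relabeling data frame with columns `id`, `original_label`,
#'   `updated_label`, covering all subjects.
#' @return the relabeled `crs_dataset`.
#' @export
apply_relabeling <- function(dataset, relabeling) {
  subjects <- dataset$subjects
  ids <- as.character(subjects$id)
  unknown <- setdiff(as.character(relabeling$id), ids)
  if (length(unknown)) {
    stop("relabeling references unknown subject id(s): ",
         paste(head(unknown, 10L), collapse = ", "))
  }
  uncovered <- setdiff(ids, as.character(relabeling$id))
  if (length(uncovered)) {
    stop("relabeling must cover all subjects; missing id(s): ",
         paste(head(uncovered, 10L), collapse = ", "))
  }
  m <- match(ids, as.character(relabeling$id))
  orig <- endpoint_label(subjects)
  stated <- as.character(relabeling$original_label)[m]
  if (any(stated != orig)) {
    stop("relabeling original_label disagrees with the dataset for id(s): ",
         paste(head(ids[stated != orig], 10L), collapse = ", "))
  }
  upd <- as.character(relabeling$updated_label)[m]
  bad <- which(!upd %in% c("none", "cause1", "cause2"))
  if (length(bad)) stop("unknown updated_label value(s): ",
                        paste(unique(upd[bad]), collapse = ", "))
  subjects$status <- ifelse(upd == "none", 0L, 1L)
  subjects$cause <- ifelse(upd == "cause1", 1L, ifelse(upd == "cause2", 2L, NA))
  competing_risks_dataset(subjects, dataset$expression, "updated")
}

#' Drop subjects from a dataset
#'
#' @param dataset a `crs_dataset`.
#' @param indices subject positions (in canonical order) to exclude.
#' @return the reduced `crs_dataset`; excluding the empty set is the identity.
#' @export
exclude_observations <- function(dataset, indices) {
  if (length(indices) == 0L) return(dataset)
  indices <- as.integer(indices)
  n <- nrow(dataset$subjects)
  if (any(is.na(indices)) || any(indices < 1L) || any(indices > n)) {
    stop("out-of-range subject index")
  }
  keep <- setdiff(seq_len(n), indices)
  if (length(keep) == 0L) stop("empty dataset refused: all subjects excluded")
  subset_dataset(dataset, keep)
}

# keep the given subject positions (internal; used by subsampling too)
subset_dataset <- function(dataset, keep) {
  structure(list(subjects = dataset$subjects[keep, , drop = FALSE],
                 expression = dataset$expression[keep, , drop = FALSE],
                 endpoint_version = dataset$endpoint_version),
            class = "crs_dataset")
}

#' Modeling configuration
#'
#' One cell of the 2^4 grid of modeling choices whose impact on selection
#' stability is quantified: the hazard model, the selection approach, the
#' endpoint version, and whether flagged outliers are excluded.
#'
#' @param hazard_type `"subdistribution"` (Fine-Gray, "sh") or
#'   `"cause_specific"` ("csh").
#' @param selection_method `"multivariable_boosting"` or `"univariate_topk"`.
#' @param endpoint `"original"` or `"updated"`.
#' @param outlier_handling `"all_observations"` or `"outliers_excluded"`.
#' @return an object of class `crs_config`.
#' @export
modeling_config <- function(hazard_type = c("subdistribution", "cause_specific"),
                            selection_method = c("multivariable_boosting", "univariate_topk"),
                            endpoint = c("original", "updated"),
                            outlier_handling = c("all_observations", "outliers_excluded")) {
  structure(list(hazard_type = match.arg(hazard_type),
                 selection_method = match.arg(selection_method),
                 endpoint = match.arg(endpoint),
                 outlier_handling = match.arg(outlier_handling)),
            class = "crs_config")
}

#' @export
print.crs_config <- function(x, ...) {
  cat(config_label(x), "\n")
  invisible(x)
}

#' Compact label for a modeling configuration
#' @param config a `crs_config`.
#' @return a string like `"sh/multi/original/all"`.
#' @export
config_label <- function(config) {
  paste(ifelse(config$hazard_type == "subdistribution", "sh", "csh"),
        ifelse(config$selection_method == "multivariable_boosting", "multi", "uni"),
        config$endpoint,
        ifelse(config$outlier_handling == "all_observations", "all", "w/o outlier"),
        sep = "/")
}

#' All 16 modeling configurations
#'
#' @param endpoints endpoint versions to include (drop `"updated"` when no
#'   endpoint update is available).
#' @return list of `crs_config` objects.
#' @export
config_grid <- function(endpoints = c("original", "updated")) {
  grid <- expand.grid(hazard_type = c("subdistribution", "cause_specific"),
                      selection_method = c("multivariable_boosting", "univariate_topk"),
                      endpoint = endpoints,
                      outlier_handling = c("all_observations", "outliers_excluded"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    modeling_config(grid$hazard_type[i], grid$selection_method[i],
                    grid$endpoint[i], grid$outlier_handling[i])
  })
}
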