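#' Construct a single-locus intensity dataset
#'
#' @param data Data frame with columns `individual_id`, `x`, `y`; one
#'   observation (replicate) per row.
#' @param locus_id Locus label.
#' @param parent1,parent2 Optional data frames of parental replicate
#'   intensities (columns `x`, `y`); both must be given or both omitted.
#' @param measure Which Sequenom intensity measure the columns carry;
#'   bookkeeping only, the model is agnostic.
#' @return An object of class `locus_dataset`.
#' @export
locus_dataset <- function(data, locus_id = "locus",
                          parent1 = NULL, parent2 = NULL,
                          measure = c("height", "area")) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(data),
            all(c("individual_id", "x", "y") %in% names(data)))
  if (xor(is.null(parent1), is.null(parent2)))
    stop("parental blocks must be both present or both absent")
  if (any(data$x < 0 | data$y < 0))
    stop("negative intensity in progeny data")
  if (any(data$x + data$y <= 0))
    stop("zero-total intensity row in progeny data")
  data$individual_id <- as.character(data$individual_id)
  structure(list(locus_id = locus_id,
                 data = data[, c("individual_id", "x", "y")],
                 parent1 = parent1, parent2 = parent2,
                 measure = measure),
            class = "locus_dataset")
}

#' @export
print.locus_dataset <- function(x, ...) {
  n <- length(unique(x$data$individual_id))
  cat(sprintf("<locus_dataset> %s: %d individuals, %d observations%s\n",
              x$locus_id, n, nrow(x$data),
              if (!is.null(x$parent1))
                sprintf(", parents %d + %d replicates",
                        nrow(x$parent1), nrow(x$parent2)) else ""))
  invisible(x)
}

#' Number of individuals in a locus dataset
#' @param dataset A `locus_dataset`.
#' @return Integer count of distinct individual ids.
#' @export
n_individuals <- function(dataset) length(unique(dataset$data$individual_id))

#' Read a locus intensity table
#'
#' Long-form delimited text, one observation per row. Parental replicates
#' may be flagged by a role column (`progeny` / `parent1` / `parent2`) or
#' supplied as separate files via [locus_dataset()].
#'
#' @param path File path.
#' @param sep Field delimiter (default tab; use "," for CSV).
#' @param id_col,x_col,y_col Column names for the individual id and the two
#'   allele-signal intensities.
#' @param role_col Optional role column name; if present in the file,
#'   rows labelled `parent1` / `parent2` become the parental blocks.
#' @param zero_policy What to do with rows where `x + y == 0`: `"error"`
#'   (default — silent data loss hides assay failure) or `"drop"` with a
#'   warning.
#' @param locus_id Locus label; defaults to the file name.
#' @return A [locus_dataset()]. Row order of the input is preserved within
#'   each block.
#' @export
read_locus <- function(path, sep = "\t",
                       id_col = "individual_id", x_col = "x", y_col = "y",
                       role_col = "role",
                       zero_policy = c("error", "drop"),
                       locus_id = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_col, x_col, y_col))
    if (!col %in% names(tab))
      stop("input is missing required column '", col, "'")
  df <- data.frame(individual_id = as.character(tab[[id_col]]),
                   x = as.numeric(tab[[x_col]]),
                   y = as.numeric(tab[[y_col]]),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$x) | is.na(df$y)))
    stop("non-numeric intensity values")
  if (any(df$x < 0 | df$y < 0))
    stop("negative intensity at row ", which(df$x < 0 | df$y < 0)[1])
  role <- if (role_col %in% names(tab)) as.character(tab[[role_col]])
          else rep("progeny", nrow(df))
  bad <- which(df$x + df$y <= 0)
  if (length(bad)) {
    if (zero_policy == "error")
      stop("row ", bad[1], " has x + y = 0; use zero_policy = \"drop\" ",
           "to discard such rows")
    warning(length(bad), " zero-total row(s) dropped")
    df <- df[-bad, , drop = FALSE]
    role <- role[-bad]
  }
  p1 <- df[role == "parent1", c("x", "y"), drop = FALSE]
  p2 <- df[role == "parent2", c("x", "y"), drop = FALSE]
  prog <- df[!(role %in% c("parent1", "parent2")), , drop = FALSE]
  if (nrow(prog) == 0L) stop("no progeny rows in ", path)
  has_parents <- nrow(p1) > 0 || nrow(p2) > 0
  if (has_parents && (nrow(p1) == 0 || nrow(p2) == 0))
    stop("parental blocks must be both present or both absent")
  locus_dataset(prog,
                locus_id = locus_id %||% basename(path),
                parent1 = if (has_parents) p1 else NULL,
                parent2 = if (has_parents) p2 else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write genotype calls to a TSV file
#'
#' One row per individual: called dosage, the posterior of that call, and
#' whether it clears the reporting threshold. Header comment lines record
#' the MAP ploidy, sigma, model parameters and configuration posterior.
#'
#' @param result A [fit_locus()] result covering every individual in
#'   `dataset`.
#' @param dataset The `locus_dataset` that was fitted.
#' @param path Output file path.
#' @param posterior_threshold Per-individual reporting threshold in
#'   `[0, 1]`; individuals with call posterior >= threshold are flagged
#'   `included = TRUE`.
#' @return The output path, invisibly.
#' @export
write_calls <- function(result, dataset, path, posterior_threshold = 0.8) {
  stopifnot(inherits(result, "polydose_fit"),
            posterior_threshold >= 0, posterior_threshold <= 1)
  ids <- unique(dataset$data$individual_id)
  if (!all(ids %in% names(result$assignment)))
    stop("result does not cover every individual in the dataset")
  post <- result$individual_posteriors
  dosage <- result$assignment[ids]
  call_post <- post[cbind(ids, as.character(dosage))]
  out <- data.frame(individual_id = ids,
                    dosage = unname(dosage),
                    posterior = unname(call_post),
                    included = unname(call_post >= posterior_threshold))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# locus=%s", dataset$locus_id),
               sprintf("# ploidy=%d sigma=%g theta=%s", result$m,
                       result$sigma, result$theta_label),
               sprintf("# config_posterior=%.6g", result$config_posterior),
               sprintf("# posterior_threshold=%g", posterior_threshold)),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a locus dataset back to delimited text
#'
#' Inverse of [read_locus()]: long-form table with a role column when
#' parental blocks are present.
#'
#' @param dataset A `locus_dataset`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return The path, invisibly.
#' @export
write_locus <- function(dataset, path, sep = "\t") {
  df <- dataset$data
  df$role <- "progeny"
  if (!is.null(dataset$parent1)) {
    mk <- function(block, role) data.frame(
      individual_id = role, x = block$x, y = block$y, role = role,
      stringsAsFactors = FALSE)
    df <- rbind(df, mk(dataset$parent1, "parent1"),
                mk(dataset$parent2, "parent2"))
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
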