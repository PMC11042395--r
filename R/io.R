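.delim_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

.read_delim <- function(path) {
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Fixed column order, 17 significant digits for floats: regression-stable
## output tables.
.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write phenotype blocks and the family table
#'
#' Delimited text, UTF-8, header row, \code{subject_id} first column.
#'
#' @param X,Y Sleep and behavior matrices with subject row names.
#' @param families Family table.
#' @param dir Output directory (created if needed).
#' @return Paths of the three files, invisibly.
#' @export
write_phenotypes <- function(X, Y, families, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sleep.csv", "behavior.csv", "family.csv"))
  .write_table(data.frame(subject_id = rownames(X), as.data.frame(X),
                          check.names = FALSE), paths[1])
  .write_table(data.frame(subject_id = rownames(Y), as.data.frame(Y),
                          check.names = FALSE), paths[2])
  .write_table(families, paths[3])
  invisible(paths)
}

#' Read phenotype blocks and the family table
#'
#' Aligns the three tables on the intersection of subject ids, drops
#' subjects with any missing value (reporting them), and returns numeric
#' matrices plus the family table.
#'
#' @param sleep_path,behavior_path,family_path Delimited files with a header
#'   and \code{subject_id} as first column.
#' @return List \code{X}, \code{Y}, \code{families}, \code{dropped}
#'   (subject ids removed for missingness).
#' @export
read_phenotypes <- function(sleep_path, behavior_path, family_path) {
  sl <- .read_delim(sleep_path)
  bh <- .read_delim(behavior_path)
  fam <- .read_delim(family_path)
  for (tb in list(sl, bh, fam))
    if (!"subject_id" %in% names(tb)) stop("subject_id column required in all files")
  as_block <- function(tb, label) {
    m <- as.matrix(tb[, setdiff(names(tb), "subject_id"), drop = FALSE])
    if (is.character(m)) {
      suppressWarnings(mn <- matrix(as.numeric(m), nrow(m), ncol(m),
                                    dimnames = dimnames(m)))
      bad <- which(is.na(mn) & !is.na(m) & m != "" & toupper(m) != "NA",
                   arr.ind = TRUE)
      if (nrow(bad))
        stop("non-numeric cell in ", label, " at row ", bad[1, 1],
             ", column ", colnames(m)[bad[1, 2]])
      m <- mn
    }
    rownames(m) <- tb$subject_id
    m
  }
  X <- as_block(sl, "sleep block")
  Y <- as_block(bh, "behavior block")
  ids <- Reduce(intersect, list(rownames(X), rownames(Y), fam$subject_id))
  if (!length(ids)) stop("empty subject intersection across files")
  n_union <- length(unique(c(rownames(X), rownames(Y), fam$subject_id)))
  if (n_union > length(ids))
    message(n_union - length(ids), " subject(s) absent from at least one file; using the intersection")
  X <- X[ids, , drop = FALSE]
  Y <- Y[ids, , drop = FALSE]
  complete <- !(rowSums(is.na(X)) > 0 | rowSums(is.na(Y)) > 0)
  dropped <- ids[!complete]
  if (length(dropped))
    message("dropped ", length(dropped), " subject(s) with missing values: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  ids <- ids[complete]
  fam <- fam[match(ids, fam$subject_id), , drop = FALSE]
  rownames(fam) <- NULL
  list(X = X[ids, , drop = FALSE], Y = Y[ids, , drop = FALSE],
       families = fam, dropped = dropped)
}

#' Write per-subject connectivity matrices
#'
#' One dense comma-delimited square matrix per subject,
#' \code{<subject_id>.csv}, plus the parcel-to-network map.
#'
#' @param matrices Named list of symmetric matrices.
#' @param map Network label per parcel.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_connectivity <- function(matrices, map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(matrices)) {
    utils::write.table(
      matrix(sprintf("%.17g", matrices[[id]]), nrow(matrices[[id]])),
      file.path(dir, paste0(id, ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  .write_table(data.frame(parcel_label = paste0("parcel_", seq_along(map)),
                          network_label = map),
               file.path(dir, "parcel_map.csv"))
  invisible(dir)
}

#' Read per-subject connectivity matrices and the parcel map
#'
#' Expects one dense square matrix file per subject; dimensions must agree
#' across subjects and with the parcel map. Matrices are symmetrized
#' (\code{(W + W') / 2}); asymmetry beyond 1e-6 triggers a warning first.
#'
#' @param dir Directory of \code{<subject_id>.csv} matrix files.
#' @param parcel_map_path Two-column delimited file (parcel_label,
#'   network_label); defaults to \code{parcel_map.csv} inside \code{dir}.
#' @return List \code{matrices} (named list) and \code{map} (character
#'   vector of network labels).
#' @export
read_connectivity <- function(dir, parcel_map_path = file.path(dir, "parcel_map.csv")) {
  pm <- .read_delim(parcel_map_path)
  if (!all(c("parcel_label", "network_label") %in% names(pm)))
    stop("parcel map needs parcel_label and network_label columns")
  map <- pm$network_label
  files <- sort(setdiff(list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE),
                        normalizePath(parcel_map_path, mustWork = FALSE)))
  files <- files[basename(files) != basename(parcel_map_path)]
  if (!length(files)) stop("no connectivity matrix files in ", dir)
  P <- length(map)
  mats <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = .delim_for(f), header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m) || nrow(m) != P)
      stop("connectivity matrix of wrong dimension: ", basename(f))
    asym <- max(abs(m - t(m)))
    if (asym > 1e-6) warning("asymmetry ", signif(asym, 3), " in ", basename(f),
                             "; symmetrizing")
    (m + t(m)) / 2
  })
  names(mats) <- sub("\\.(csv|tsv)$", "", basename(files))
  list(matrices = mats, map = map)
}

#' Serialize a fitted CCA model to a structured text file
#'
#' JSON container with weights, standardization parameters and canonical
#' correlations at full floating-point precision — sufficient for exact
#' score reproduction by [read_cca_model()] + [project_scores()].
#'
#' @param model A [fit_cca()] model.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cca_model <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized CCA model
#'
#' @param path File written by [write_cca_model()].
#' @return A \code{cca_model} object.
#' @export
read_cca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sleep_weights", "behavior_weights"))
    obj[[f]] <- as.matrix(obj[[f]])
  for (f in c("x_center", "x_scale", "y_center", "y_scale"))
    if (!is.null(obj[[f]])) obj[[f]] <- unlist(obj[[f]])
  structure(obj, class = "cca_model")
}
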