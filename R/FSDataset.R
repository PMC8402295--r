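#' Construct an FSDataset
#'
#' @param features numeric matrix, samples in rows and features in columns.
#' @param labels vector or factor of class labels, one per sample row.
#' @param featureNames optional character vector of unique feature names;
#'   defaults to `colnames(features)`, or `f1, f2, ...` when absent.
#' @param missingMask optional logical matrix marking originally-missing
#'   cells; defaults to `is.na(features)`.
#'
#' @return an [FSDataset-class] object.
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' d <- FSDataset(m, rep(c("a", "b"), 5))
#' nFeatures(d)
#' @export
FSDataset <- function(features, labels, featureNames = NULL,
                      missingMask = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!is.null(featureNames)) {
    colnames(features) <- featureNames
  } else if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  if (is.null(missingMask)) missingMask <- is.na(features)
  new("FSDataset",
      features = features,
      labels = droplevels(as.factor(labels)),
      missingMask = missingMask)
}

#' Accessors for FSDataset
#'
#' `featureMatrix` returns the samples-by-features numeric matrix;
#' `classLabels` the label factor; `featureNames` the feature (column)
#' names; `missingMask` the logical mask of originally-missing cells;
#' `nSamples` and `nFeatures` the two dimensions.
#'
#' @param x an [FSDataset-class].
#' @return the corresponding slot or dimension.
#' @name FSDataset-accessors
NULL

#' @rdname FSDataset-accessors
#' @export
setMethod("featureMatrix", "FSDataset", function(x) x@features)

#' @rdname FSDataset-accessors
#' @export
setMethod("classLabels", "FSDataset", function(x) x@labels)

#' @rdname FSDataset-accessors
#' @export
setMethod("featureNames", "FSDataset", function(x) colnames(x@features))

#' @rdname FSDataset-accessors
#' @export
setMethod("missingMask", "FSDataset", function(x) x@missingMask)

#' @rdname FSDataset-accessors
#' @export
setMethod("nSamples", "FSDataset", function(x) nrow(x@features))

#' @rdname FSDataset-accessors
#' @export
setMethod("nFeatures", "FSDataset", function(x) ncol(x@features))

setMethod("show", "FSDataset", function(object) {
  tab <- table(object@labels)
  cat("FSDataset:", nrow(object@features), "samples x",
      ncol(object@features), "features\n")
  cat("classes:",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
  nm <- sum(object@missingMask)
  if (nm > 0) cat("originally missing cells:", nm, "\n")
  invisible(NULL)
})

#' Read a tabular classification dataset from CSV or ARFF
#'
#' CSV files need a header row; each row is one sample.  The cells `"?"`,
#' `""` and `"NA"` in feature columns are treated as missing and recorded
#' in the returned object's missing mask.  ARFF files are read with
#' [foreign::read.arff()] (numeric attributes plus one nominal class
#' attribute; `"?"` is missing).
#'
#' @param path path to the file.
#' @param labelColumn name of the class-label column.
#' @param dialect `"csv"` (default) or `"arff"`.
#'
#' @return an [FSDataset-class]; feature column order is preserved from the
#'   file.
#' @export
readTabular <- function(path, labelColumn, dialect = c("csv", "arff")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
                          na.strings = c("?", "", "NA"),
                          stringsAsFactors = FALSE)
  } else {
    df <- foreign::read.arff(path)
  }
  if (!labelColumn %in% names(df))
    stop("label column '", labelColumn, "' not found in ", path)
  fcols <- setdiff(names(df), labelColumn)
  if (anyDuplicated(fcols))
    stop("duplicate feature names: ",
         paste(unique(fcols[duplicated(fcols)]), collapse = ", "))
  labels <- df[[labelColumn]]
  if (anyNA(labels)) stop("missing values in the label column")
  feats <- lapply(fcols, function(nm) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      out <- suppressWarnings(as.numeric(as.character(v)))
      if (all(is.na(out)) && !all(is.na(v)))
        stop("feature column '", nm, "' has no numeric values")
      v <- out
    }
    v
  })
  m <- do.call(cbind, feats)
  colnames(m) <- fcols
  FSDataset(m, labels)
}

#' Class-wise mean imputation
#'
#' Replaces each missing cell by the mean of the observed values of the
#' same feature within the same class.  If a (class, feature) group has no
#' observed value at all, the global feature mean is used instead.  Observed
#' cells are never changed, so the operation is idempotent.
#'
#' @param x an [FSDataset-class]; cells that are `NA` in the feature matrix
#'   are imputed.
#' @return an [FSDataset-class] with no missing values; the missing mask is
#'   preserved as an audit of which cells were filled.
#' @export
imputeClasswiseMean <- function(x) {
  stopifnot(is(x, "FSDataset"))
  f <- featureMatrix(x)
  if (!anyNA(f)) return(x)
  y <- classLabels(x)
  bad <- colSums(!is.na(f)) == 0L
  if (any(bad))
    stop("feature(s) entirely missing, cannot impute: ",
         paste(colnames(f)[bad], collapse = ", "))
  globalMean <- colMeans(f, na.rm = TRUE)
  for (cl in levels(y)) {
    rows <- which(y == cl)
    sub <- f[rows, , drop = FALSE]
    miss <- is.na(sub)
    if (!any(miss)) next
    clMean <- colMeans(sub, na.rm = TRUE)
    # group entirely missing within this class -> global fallback
    clMean[is.nan(clMean)] <- globalMean[is.nan(clMean)]
    fill <- matrix(clMean, nrow(sub), ncol(sub), byrow = TRUE)
    sub[miss] <- fill[miss]
    f[rows, ] <- sub
  }
  new("FSDataset", features = f, labels = y, missingMask = missingMask(x))
}

#' Standardize then min-max normalize every feature
#'
#' Each feature column is z-scored (mean 0, sample standard deviation with
#' the n-1 denominator) and then rescaled to `[0, 1]` by its min and max.
#' Constant columns map to 0.5 everywhere, keeping them inert for
#' distance-based methods.  The composition is invariant to any positive
#' affine transform of an input column.
#'
#' @param x an [FSDataset-class] without missing values (impute first).
#' @return an [FSDataset-class] whose features all lie in `[0, 1]`.
#' @export
standardizeNormalize <- function(x) {
  stopifnot(is(x, "FSDataset"))
  f <- featureMatrix(x)
  if (anyNA(f))
    stop("missing values present; run imputeClasswiseMean() first")
  f <- apply(f, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0.5, length(v)))
    z <- (v - mean(v)) / s
    (z - min(z)) / (max(z) - min(z))
  })
  dimnames(f) <- dimnames(featureMatrix(x))
  new("FSDataset", features = f, labels = classLabels(x),
      missingMask = missingMask(x))
}

#' Write an FSDataset to CSV
#'
#' Writes one sample per row with a header, feature columns first and the
#' label in column `class` (or `labelColumn`).  Cells flagged in the
#' missing mask are written as `"?"`.
#'
#' @param x an [FSDataset-class].
#' @param path output file path.
#' @param labelColumn name for the label column.
#' @return `path`, invisibly.
#' @export
writeTabular <- function(x, path, labelColumn = "class") {
  f <- featureMatrix(x)
  df <- as.data.frame(f)
  mm <- missingMask(x)
  if (any(mm)) {
    for (j in which(colSums(mm) > 0)) {
      col <- as.character(df[[j]])
      col[mm[, j]] <- "?"
      df[[j]] <- col
    }
  }
  df[[labelColumn]] <- as.character(classLabels(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
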