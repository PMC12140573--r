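#' Construct a PortraitExperiment
#'
#' Assemble single-trial oscillatory portraits and trial metadata into the
#' package's central container.
#'
#' @param elements numeric matrix of element values, either 48 x n_trials
#'   (rows in the frozen element order) or n_trials x 48 (columns named as in
#'   [elementNames()]); a trials x 48 matrix is transposed automatically.
#' @param subject character/factor of subject identifiers, one per trial.
#' @param category trial category labels, a subset of [trialCategories()].
#' @param movement_error signed movement-direction error per trial
#'   (perpendicular deviation at peak velocity, arbitrary units).
#' @param movement_duration movement duration per trial in seconds.
#' @param metadata optional list stored as experiment metadata (e.g. the
#'   generating configuration and ground truth for synthetic tables).
#' @return A [PortraitExperiment-class] object.
#' @examples
#' pe <- PortraitExperiment(matrix(rnorm(48 * 10), 48, 10,
#'                                 dimnames = list(elementNames(), NULL)),
#'                          subject = rep("S01", 10),
#'                          category = rep("NR-Hit", 10),
#'                          movement_error = rnorm(10),
#'                          movement_duration = rep(0.8, 10))
#' pe
#' @export
PortraitExperiment <- function(elements, subject, category, movement_error,
                               movement_duration, metadata = list()) {
    en <- elementNames()
    if (nrow(elements) != 48L && ncol(elements) == 48L)
        elements <- t(elements)
    if (nrow(elements) != 48L)
        stop("'elements' must have 48 rows (or columns)")
    if (is.null(rownames(elements))) rownames(elements) <- en
    elements <- elements[en, , drop = FALSE]
    info <- elementInfo()
    cd <- DataFrame(subject = as.character(subject),
                    category = as.character(category),
                    movement_error = as.numeric(movement_error),
                    movement_duration = as.numeric(movement_duration))
    if (is.null(colnames(elements)))
        colnames(elements) <- sprintf("trial%04d", seq_len(ncol(elements)))
    rownames(cd) <- colnames(elements)
    se <- SummarizedExperiment(assays = list(elements = elements),
                               rowData = DataFrame(info[, c("region", "epoch", "band")],
                                                   row.names = en),
                               colData = cd, metadata = metadata)
    new("PortraitExperiment", se)
}

#' @describeIn PortraitExperiment element values as a trials x 48 matrix
#'   (the orientation used by the statistical modules).
#' @param x a `PortraitExperiment`.
#' @export
elementMatrix <- function(x) t(assay(x, "elements"))

setMethod("show", "PortraitExperiment", function(object) {
    cat("PortraitExperiment:", ncol(object), "trials,",
        nrow(object), "oscillatory elements\n")
    tab <- table(object$category)
    cat("  subjects:", length(unique(object$subject)),
        " categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
})

#' Read / write portrait tables as CSV
#'
#' The on-disk interchange format is a 52-column CSV: `subject`, `category`,
#' `movement_error`, `movement_duration`, then the 48 element columns named
#' `IC{r}_{epoch}_{band}` in the frozen order.
#'
#' @param file path to a CSV file.
#' @param x a [PortraitExperiment-class].
#' @return `readPortraits` returns a `PortraitExperiment`; `writePortraits`
#'   returns `file` invisibly.
#' @export
readPortraits <- function(file) {
    df <- utils::read.csv(file, check.names = FALSE)
    need <- c("subject", "category", "movement_error", "movement_duration",
              elementNames())
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("portrait CSV is missing column(s): ", paste(miss, collapse = ", "))
    PortraitExperiment(as.matrix(df[, elementNames()]),
                       subject = df$subject, category = df$category,
                       movement_error = df$movement_error,
                       movement_duration = df$movement_duration)
}

#' @rdname readPortraits
#' @export
writePortraits <- function(x, file) {
    df <- data.frame(subject = x$subject, category = x$category,
                     movement_error = x$movement_error,
                     movement_duration = x$movement_duration,
                     elementMatrix(x), check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE)
    invisible(file)
}

## Extract the trials x p predictor matrix for a feature request:
## "portrait" (all 48 elements) or a vector of element names.
featureMatrix <- function(x, features) {
    em <- elementMatrix(x)
    if (identical(features, "portrait")) return(em)
    bad <- setdiff(features, colnames(em))
    if (length(bad))
        stop("unknown element feature(s): ", paste(bad, collapse = ", "))
    em[, features, drop = FALSE]
}
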