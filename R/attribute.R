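#' Patient age in days from calendar dates
#'
#' Exact calendar-day difference between study date and birth date (the
#' numeric encoding used for the age tag).
#'
#' @param study_date,birth_date dates (or strings coercible by [as.Date()]).
#' @return integer vector of whole days.
#' @export
encode_age <- function(study_date, birth_date) {
  s <- as.Date(study_date); b <- as.Date(birth_date)
  if (any(b > s)) stop2("birth date after study date")
  as.integer(s - b)
}

#' Numerically encode a metadata tag
#'
#' Numeric tags become a single standardized column; categorical tags become
#' reference-level indicator columns (levels - 1 of them; missing values get
#' their own level). A constant tag encodes to a zero-column matrix.
#'
#' @param values tag values (numeric, character or factor).
#' @param name tag name.
#' @return object of class `encoded_tag`: list with `name`, `kind`, and
#'   `encoding` (n x k numeric matrix).
#' @export
encode_tag <- function(values, name = deparse(substitute(values))) {
  n <- length(values)
  if (is.numeric(values)) {
    v <- values
    if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
    s <- stats::sd(v)
    enc <- if (is.na(s) || s == 0) {
      matrix(numeric(0), n, 0)
    } else {
      matrix((v - mean(v)) / s, n, 1, dimnames = list(NULL, name))
    }
    kind <- "numeric"
  } else {
    f <- as.character(values)
    f[is.na(f) | f == ""] <- "(missing)"
    f <- factor(f)
    if (nlevels(f) < 2) {
      enc <- matrix(numeric(0), n, 0)
    } else {
      enc <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(enc) <- paste0(name, ":", levels(f)[-1])
    }
    kind <- "categorical"
  }
  structure(list(name = name, kind = kind, encoding = enc),
            class = "encoded_tag")
}

# Pooled R^2 of a multivariate least-squares fit of `coords` (n x 2) on a
# column-encoded design: 1 - pooled RSS / pooled TSS about column means.
# Rank deficiency is handled by the SVD pseudoinverse.
pooled_r2 <- function(coords, enc) {
  n <- nrow(coords)
  Yc <- sweep(coords, 2, colMeans(coords))
  tss <- sum(Yc^2)
  if (tss == 0) return(0)
  if (ncol(enc) == 0) return(0)
  Xc <- sweep(enc, 2, colMeans(enc))
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos)) return(0)
  U <- sv$u[, pos, drop = FALSE]
  fitted <- U %*% crossprod(U, Yc)
  rss <- sum((Yc - fitted)^2)
  max(0, min(1, 1 - rss / tss))
}

#' Explained variance (R^2) of one tag on 2-D embedding coordinates
#'
#' Least-squares fit of both coordinate columns on the tag encoding;
#' R^2 = 1 - (pooled residual SS) / (pooled total SS about the column
#' means). A constant tag yields r2 = 0 with a warning, never NaN.
#'
#' @param coords numeric matrix n x 2.
#' @param tag an `encoded_tag` (or raw values, encoded on the fly).
#' @return object of class `attribution_result`: list with `tag`, `r2`, `n`.
#' @export
tag_r2 <- function(coords, tag) {
  coords <- as.matrix(coords)
  if (!inherits(tag, "encoded_tag")) tag <- encode_tag(tag, "tag")
  if (nrow(tag$encoding) != nrow(coords)) {
    stop2("tag encoding has ", nrow(tag$encoding), " rows; coords have ",
          nrow(coords))
  }
  if (ncol(tag$encoding) == 0) {
    warning("tag '", tag$name, "' is constant; r2 = 0")
    r2 <- 0
  } else {
    r2 <- pooled_r2(coords, tag$encoding)
  }
  structure(list(tag = tag$name, r2 = r2, n = nrow(coords)),
            class = "attribution_result")
}

#' Cumulative R^2 of a set of tags
#'
#' Joint least-squares regression on the column-concatenated encodings of
#' all tags (pseudoinverse handles rank deficiency), so the result is
#' monotone: a superset of tags never explains less than a subset. The
#' empty set returns 0.
#'
#' @param coords numeric matrix n x 2.
#' @param tags list of `encoded_tag` objects.
#' @return an `attribution_result` with `tag = "(cumulative)"`.
#' @export
cumulative_r2 <- function(coords, tags) {
  coords <- as.matrix(coords)
  if (length(tags) == 0) {
    return(structure(list(tag = "(cumulative)", r2 = 0, n = nrow(coords)),
                     class = "attribution_result"))
  }
  enc <- do.call(cbind, lapply(tags, function(t) t$encoding))
  structure(list(tag = "(cumulative)", r2 = pooled_r2(coords, enc),
                 n = nrow(coords)),
            class = "attribution_result")
}

#' Rank tags by explained variance
#'
#' @param coords numeric matrix n x 2.
#' @param tags named list of `encoded_tag` objects.
#' @return `data.frame` (tag, r2, n, rank) in descending r2 order; ties
#'   break alphabetically by tag name.
#' @export
rank_tags <- function(coords, tags) {
  res <- lapply(tags, function(t) suppressWarnings(tag_r2(coords, t)))
  df <- data.frame(tag = vapply(res, `[[`, "", "tag"),
                   r2 = vapply(res, `[[`, 0, "r2"),
                   n = vapply(res, `[[`, 0L, "n"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$r2, df$tag), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Attribution analysis of a cohort's embedding
#'
#' Convenience wrapper reproducing the captured-features analysis: encodes
#' the standard DICOM-derived tags (label, manufacturer, age in days,
#' department, sex, view) from a manifest, ranks their individual R^2
#' against the 2-D coordinates, and reports the cumulative R^2 of the
#' non-label tags.
#'
#' @param coords numeric matrix n x 2, rows aligned with `manifest`.
#' @param manifest cohort manifest rows matching `coords`.
#' @return list with `ranking` (`data.frame` from [rank_tags()]) and
#'   `cumulative_metadata_r2` (manufacturer + age + department).
#' @export
attribute_cohort <- function(coords, manifest) {
  tags <- list(
    label = encode_tag(manifest$label, "label"),
    manufacturer = encode_tag(manifest$manufacturer, "manufacturer"),
    age_days = encode_tag(
      encode_age(manifest$study_date, manifest$birth_date), "age_days"),
    department = encode_tag(manifest$department, "department"),
    sex = encode_tag(manifest$sex, "sex"),
    view = encode_tag(manifest$view, "view"))
  ranking <- rank_tags(coords, tags)
  cum <- cumulative_r2(coords, tags[c("manufacturer", "age_days",
                                      "department")])
  list(ranking = ranking, cumulative_metadata_r2 = cum$r2)
}

#' Write attribution results as CSV
#'
#' @param ranking `data.frame` from [rank_tags()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_attribution <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}

#' Bar chart of tag R^2 values
#'
#' @param ranking `data.frame` from [rank_tags()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_attribution <- function(ranking, ...) {
  invisible(graphics::barplot(ranking$r2, names.arg = ranking$tag,
                              ylab = expression(R^2), las = 2,
                              col = "steelblue", ...))
}
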