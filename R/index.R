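#' Default Physical Function Index mapping
#'
#' The Physical Function Index is an SF-36 proxy built from five survey
#' limitation items. Each item's 5-level difficulty code is collapsed to
#' SF-36-style points (3 = not at all difficult; 2 = only a little or
#' somewhat difficult; 1 = very difficult or can't do at all) and weighted:
#' climbing stairs counts double and walking a quarter-mile triple, because
#' those items stand in for two and three SF-36 questions respectively. A
#' person with no limitations scores 24 raw points, so the index is the point
#' total divided by 24, expressed as a percentage.
#'
#' @return A list with components `weights` (named integer vector over the
#'   five index items), `points` (length-5 map from difficulty code to
#'   points) and `denominator` (24).
#' @export
#' @examples
#' default_index_mapping()
default_index_mapping <- function() {
  list(
    weights = c(push = 1L, lift = 1L, climb = 2L, stoop = 1L, walk = 3L),
    points = c(3L, 2L, 2L, 1L, 1L),
    denominator = 24L)
}

validate_index_mapping <- function(mapping) {
  if (!all(mapping$points %in% 1:3)) {
    stop("index mapping: points must be in {1, 2, 3}", call. = FALSE)
  }
  if (mapping$denominator != 3 * sum(mapping$weights)) {
    stop("index mapping: denominator must equal 3 x sum of weights",
         call. = FALSE)
  }
  invisible(mapping)
}

#' Score the Physical Function Index
#'
#' Computes the Physical Function Index for one or more respondents from the
#' five mapped limitation items. Sitting, reaching and standing are
#' deliberately excluded from the index; they are carried through the
#' analysis as separate covariates.
#'
#' @param respondent a list or data frame with limitation items in columns
#'   `lim_walk`, `lim_climb`, `lim_stoop`, `lim_lift`, `lim_push` (codes
#'   1-5), and, when `msk_only = TRUE`, logical cause columns `cause_back`,
#'   `cause_injury`, `cause_msk`, `cause_arthritis`.
#' @param mapping an index mapping, see [default_index_mapping()].
#' @param msk_only if `TRUE` (default), respondents with no musculoskeletal
#'   cause attributed to their limitations are treated as having no
#'   limitations (all items recoded to 1), reflecting an analysis restricted
#'   to MSK-attributable limitation.
#' @return A list (single respondent) or data frame (several) with `value`
#'   (percentage in [33.33, 100]) and `raw_points` (integer in [8, 24]).
#' @export
#' @examples
#' r <- list(lim_walk = 3, lim_climb = 1, lim_stoop = 1, lim_lift = 1,
#'           lim_push = 1, cause_arthritis = TRUE)
#' score_index(r)  # 21 points, 87.5%
score_index <- function(respondent, mapping = default_index_mapping(),
                        msk_only = TRUE) {
  validate_index_mapping(mapping)
  single <- !is.data.frame(respondent)
  items <- names(mapping$weights)
  cols <- paste0("lim_", items)

  get_col <- function(col) {
    v <- respondent[[col]]
    if (is.null(v)) {
      stop(sprintf("missing limitation item '%s'", col), call. = FALSE)
    }
    v <- as.integer(as.character(v))
    if (anyNA(v) || any(v < 1L | v > 5L)) {
      stop(sprintf("invalid limitation code in '%s': codes must be 1-5", col),
           call. = FALSE)
    }
    v
  }
  codes <- lapply(cols, get_col)
  names(codes) <- items
  n <- length(codes[[1]])

  if (isTRUE(msk_only)) {
    has_cause <- Reduce(`|`, lapply(msk_cause_cols, function(cc) {
      v <- respondent[[cc]]
      if (is.null(v)) rep(FALSE, n) else as.logical(v)
    }))
    codes <- lapply(codes, function(v) ifelse(has_cause, v, 1L))
  }

  raw <- rep(0L, n)
  for (it in items) {
    raw <- raw + mapping$weights[[it]] * mapping$points[codes[[it]]]
  }
  value <- 100 * raw / mapping$denominator
  if (single) list(value = value, raw_points = as.integer(raw))
  else data.frame(value = value, raw_points = as.integer(raw))
}

#' Append the Physical Function Index to a cohort table
#'
#' @param cohort a cohort data frame, see [generate_cohort()].
#' @inheritParams score_index
#' @return `cohort` with an added numeric column `pf_index` (0-100 scale).
#' @export
add_function_index <- function(cohort, mapping = default_index_mapping(),
                               msk_only = TRUE) {
  sc <- score_index(cohort, mapping = mapping, msk_only = msk_only)
  cohort$pf_index <- sc$value
  cohort
}

#' Score the SF-36 physical-function scale
#'
#' The original SF-36 physical-functioning scale: ten items, each answered
#' "not limited at all" (3 points), "limited a little" (2) or "limited a lot"
#' (1); the point total is divided by 30 and expressed as a percentage.
#'
#' @param responses a length-10 vector, either integer codes 1-3 (1 =
#'   limited a lot, 3 = not limited at all) or the character labels
#'   `"limited_a_lot"`, `"limited_a_little"`, `"not_limited"`.
#' @return The scale value, a percentage in [33.33, 100].
#' @export
#' @examples
#' score_sf36_pf(rep(3, 10))  # 100
#' score_sf36_pf(c(rep("not_limited", 5), rep("limited_a_little", 5)))
score_sf36_pf <- function(responses) {
  if (length(responses) != 10) {
    stop("SF-36 physical function requires exactly 10 responses",
         call. = FALSE)
  }
  if (is.character(responses) || is.factor(responses)) {
    map <- c(limited_a_lot = 1L, limited_a_little = 2L, not_limited = 3L)
    pts <- map[as.character(responses)]
    if (anyNA(pts)) stop("unknown SF-36 response label", call. = FALSE)
  } else {
    pts <- as.integer(responses)
    if (anyNA(pts) || any(pts < 1L | pts > 3L)) {
      stop("SF-36 responses must be coded 1-3", call. = FALSE)
    }
  }
  100 * sum(pts) / 30
}
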