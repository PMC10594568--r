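#' Build a codebook describing the columns of a categorical survey dataset
#'
#' A codebook assigns every analysis column a role and, for categorical
#' variables, an ordered set of category labels. Roles follow the usual
#' survey-LCA layout: `indicator` columns define the latent classes,
#' `covariate` columns predict class membership, and at most one column each
#' carries the survey `weight`, the sampling `cluster` (e.g. school) and the
#' `group` (e.g. survey wave).
#'
#' @param variables A data frame (or tibble) with columns `name`, `role`
#'   (one of `"indicator"`, `"covariate"`, `"weight"`, `"cluster"`,
#'   `"group"`), `categories` (list-column of character vectors; ignored for
#'   weight/cluster/group) and optionally `reference` (reference category for
#'   covariates; defaults to the first category).
#' @return A `lcat_codebook` object (a tibble with class attributes).
#' @examples
#' cb <- codebook(tibble::tibble(
#'   name = c("smoke", "sex", "wt", "school", "wave"),
#'   role = c("indicator", "covariate", "weight", "cluster", "group"),
#'   categories = list(c("no", "yes"), c("male", "female"), NULL, NULL, NULL)
#' ))
#' indicator_names(cb)
#' @export
codebook <- function(variables) {
  stopifnot(is.data.frame(variables))
  v <- tibble::as_tibble(variables)
  if (!all(c("name", "role", "categories") %in% names(v))) {
    abort_config("`variables` needs columns name, role, categories")
  }
  if (!"reference" %in% names(v)) v$reference <- NA_character_
  ok_roles <- c("indicator", "covariate", "weight", "cluster", "group")
  bad <- setdiff(unique(v$role), ok_roles)
  if (length(bad)) abort_config(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(v$name)) abort_config("duplicate variable names in codebook")
  for (r in c("weight", "cluster", "group")) {
    if (sum(v$role == r) > 1) abort_config(paste0("at most one ", r, " variable allowed"))
  }
  for (i in which(v$role == "indicator")) {
    if (length(v$categories[[i]]) < 2) {
      abort_config(paste0("indicator ", v$name[i], " needs >= 2 categories"))
    }
  }
  for (i in which(v$role == "covariate")) {
    cats <- v$categories[[i]]
    if (length(cats) < 2) abort_config(paste0("covariate ", v$name[i], " needs >= 2 categories"))
    if (is.na(v$reference[i])) v$reference[i] <- cats[[1]]
    if (!v$reference[i] %in% cats) {
      abort_config(paste0("reference level '", v$reference[i], "' of ", v$name[i],
                          " is not one of its categories"))
    }
  }
  structure(v, class = c("lcat_codebook", class(v)))
}

#' @export
print.lcat_codebook <- function(x, ...) {
  cat("<lcat_codebook> ", sum(x$role == "indicator"), " indicators, ",
      sum(x$role == "covariate"), " covariates\n", sep = "")
  NextMethod()
}

#' Accessors for codebook roles
#' @param cb A [codebook()].
#' @return Character vector of column names (or `NULL` for the scalar roles
#'   when absent).
#' @export
indicator_names <- function(cb) cb$name[cb$role == "indicator"]

#' @rdname indicator_names
#' @export
covariate_names <- function(cb) cb$name[cb$role == "covariate"]

#' @rdname indicator_names
#' @export
weight_name <- function(cb) if (any(cb$role == "weight")) cb$name[cb$role == "weight"] else NULL

#' @rdname indicator_names
#' @export
cluster_name <- function(cb) if (any(cb$role == "cluster")) cb$name[cb$role == "cluster"] else NULL

#' @rdname indicator_names
#' @export
group_name <- function(cb) if (any(cb$role == "group")) cb$name[cb$role == "group"] else NULL

# number of categories per indicator, named
indicator_ncat <- function(cb) {
  j <- which(cb$role == "indicator")
  stats::setNames(vapply(cb$categories[j], length, 1L), cb$name[j])
}

indicator_categories <- function(cb, name) cb$categories[[match(name, cb$name)]]

covariate_reference <- function(cb, name) cb$reference[[match(name, cb$name)]]

# names of the dummy columns implied by the covariates (non-reference levels)
covariate_dummy_names <- function(cb) {
  out <- character(0)
  for (i in which(cb$role == "covariate")) {
    lv <- setdiff(cb$categories[[i]], cb$reference[i])
    out <- c(out, paste0(cb$name[i], ":", lv))
  }
  out
}

#' Read / write a codebook as JSON
#'
#' @param path File path.
#' @return `read_codebook()` returns a [codebook()]; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  v <- tibble::tibble(
    name = vapply(j$variables, function(x) x$name, ""),
    role = vapply(j$variables, function(x) x$role, ""),
    categories = lapply(j$variables, function(x) {
      if (is.null(x$categories)) NULL else unlist(x$categories)
    }),
    reference = vapply(j$variables, function(x) x$reference %||% NA_character_, "")
  )
  codebook(v)
}

#' @rdname read_codebook
#' @param cb A [codebook()].
#' @export
write_codebook <- function(cb, path) {
  vars <- lapply(seq_len(nrow(cb)), function(i) {
    x <- list(name = cb$name[i], role = cb$role[i])
    if (!is.null(cb$categories[[i]])) x$categories <- as.list(cb$categories[[i]])
    if (!is.na(cb$reference[i])) x$reference <- cb$reference[i]
    x
  })
  jsonlite::write_json(list(variables = vars), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The default adolescent health & wellbeing codebook
#'
#' Twelve health and wellbeing indicators measured on English 15-year-olds
#' across four survey waves: six binary (weekly alcohol use, current smoking,
#' lifetime cannabis use, sexual activity, daily e-media use, ease of
#' communication with parents) and six four-level ordinal items treated as
#' nominal categoricals (exercise, fruit & vegetable consumption, perceived
#' academic achievement, pressure from schoolwork, classmate support, life
#' satisfaction). Covariates are sex (reference male) and the three-level
#' family affluence scale (reference low). Weight, school cluster and survey
#' wave columns complete the layout.
#'
#' @return A [codebook()].
#' @export
default_codebook <- function() {
  four <- function(worst, rest) c(worst, rest)
  codebook(tibble::tibble(
    name = c("alcohol_weekly", "smoking", "cannabis", "sexual_activity",
             "emedia_daily", "parent_comm_hard",
             "exercise", "fruit_veg", "achievement", "school_pressure",
             "classmate_support", "life_satisfaction",
             "sex", "fas", "weight", "school", "wave"),
    role = c(rep("indicator", 12), "covariate", "covariate",
             "weight", "cluster", "group"),
    categories = list(
      c("not_weekly", "weekly"),
      c("non_smoker", "smoker"),
      c("never", "any_use"),
      c("never", "had_intercourse"),
      c("not_daily", "daily"),
      c("easy", "none_easy"),            # risky level: no parent easy to talk to
      c("low", "mid_low", "mid_high", "high"),
      c("low", "mid_low", "mid_high", "high"),
      c("below_average", "average", "good", "very_good"),
      c("a_lot", "some", "a_little", "not_at_all"),
      c("low", "mid_low", "mid_high", "high"),
      c("low", "mid_low", "mid_high", "high"),
      c("male", "female"),
      c("low", "middle", "high"),
      NULL, NULL, NULL
    ),
    reference = c(rep(NA_character_, 12), "male", "low", NA, NA, NA)
  ))
}
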