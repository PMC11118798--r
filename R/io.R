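# Shared time-course table dialect: one row per
# (participant, group, condition, region, subregion), volume columns
# v001..vNNN; covariates CSV keyed by participant.

#' Write sub-region time-courses of a cohort to CSV
#'
#' @param cohort a `sapm_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(cohort, path) {
  rows <- list()
  for (p in cohort$participants) for (cond in names(p$conditions)) {
    tc <- p$conditions[[cond]]$timecourses
    dn <- dimnames(tc)[[1]]
    for (r in seq_len(dim(tc)[1])) for (s in seq_len(dim(tc)[2])) {
      v <- as.list(tc[r, s, ])
      names(v) <- sprintf("v%03d", seq_len(dim(tc)[3]))
      rows[[length(rows) + 1L]] <- c(
        list(participant = p$id, group = p$group, condition = cond,
             region = dn[r], subregion = s), v)
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sub-region time-course table
#'
#' @param path CSV in the shared dialect.
#' @return data.frame with metadata columns and `v...` volume columns.
#' @export
read_timecourses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Extract one participant/condition observation array from a table
#'
#' @param tc data.frame from [read_timecourses()].
#' @param participant,condition selectors.
#' @return array regions x subregions x volumes.
#' @export
timecourse_array <- function(tc, participant, condition) {
  sel <- tc[tc$participant == participant & tc$condition == condition, ]
  if (!nrow(sel)) stop("no rows for ", participant, "/", condition,
                       call. = FALSE)
  vcols <- grep("^v[0-9]+$", names(sel), value = TRUE)
  regions <- unique(sel$region)
  S <- max(sel$subregion)
  out <- array(NA_real_, c(length(regions), S, length(vcols)),
               dimnames = list(regions, NULL, NULL))
  for (i in seq_len(nrow(sel)))
    out[sel$region[i], sel$subregion[i], ] <- as.numeric(sel[i, vcols])
  out
}

#' Serialize a fit result to JSON (+ latent CSV)
#'
#' @param fit a `sapm_fit`.
#' @param path output `.json` path; latent time-courses go to a sibling
#'   `_latents.csv`.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- list(db = as.list(fit$db),
              subregion_choice = as.list(fit$subregion_choice),
              r2_total = fit$r2_total,
              r2_by_region = as.list(fit$r2_by_region),
              n_iter = fit$n_iter, converged = fit$converged, sse = fit$sse)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  lat <- do.call(rbind, lapply(fit$latents, function(l)
    data.frame(latent = l$name, t(l$series))))
  utils::write.csv(lat, sub("\\.json$", "_latents.csv", path),
                   row.names = FALSE)
  invisible(path)
}
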