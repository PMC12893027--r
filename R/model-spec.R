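#' Random-regression model specification
#'
#' Describes the single-trait random-regression model: fixed herd-year-season
#' and insemination-age classes plus a fixed regression on the Legendre
#' basis; random animal intercept+slope coefficients with a relationship
#' matrix; i.i.d. permanent-environment coefficients; and an optional
#' scalar service-sire effect.
#'
#' @param trait Trait name (`"NRR56"`, `"CTFS"`, `"DO"`, or any label
#'   present in the phenotype table).
#' @param basis An [legendre_basis()] for the parity gradient.
#' @param fixed Character vector of factor columns of the phenotype table to
#'   fit as fixed class effects.
#' @param include_pe Fit permanent-environment regression coefficients?
#' @param service_sire Fit the random service-sire effect? Default (`NULL`)
#'   follows the trait convention: included for NRR56 and DO, not for CTFS.
#' @return An object of class `rr_model_spec`.
#' @export
rr_model_spec <- function(trait, basis = NULL,
                          fixed = c("hys", "age_class"),
                          include_pe = TRUE, service_sire = NULL) {
  if (is.null(basis)) {
    basis <- if (trait == "NRR56") legendre_basis(0, 6) else legendre_basis(1, 6)
  }
  if (is.null(service_sire)) service_sire <- trait %in% c("NRR56", "DO")
  structure(
    list(trait = trait, basis = basis, fixed = fixed,
         include_pe = isTRUE(include_pe),
         service_sire = isTRUE(service_sire)),
    class = "rr_model_spec"
  )
}

#' @export
print.rr_model_spec <- function(x, ...) {
  cat(sprintf("<rr_model_spec> %s ~ %s + legendre(order %d)%s%s\n",
              x$trait, paste(x$fixed, collapse = " + "), x$basis$order,
              if (x$include_pe) " + pe" else "",
              if (x$service_sire) " + service_sire" else ""))
  invisible(x)
}

## Shared design preparation: orders records animal-major (animals grouped
## by parity pattern so the residual covariance is block-constant within a
## group), builds the fixed-effect matrix and the per-record basis.
rr_design <- function(phenotypes, spec, relationship = NULL) {
  ph <- as_tibble(phenotypes)
  ph <- ph[ph$trait == spec$trait, , drop = FALSE]
  if (!nrow(ph)) abort(sprintf("no records for trait '%s'.", spec$trait))
  missing_cols <- setdiff(c("animal_id", "parity", "value", spec$fixed),
                          names(ph))
  if (length(missing_cols)) {
    abort(sprintf("phenotype table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  b <- spec$basis
  if (any(ph$parity < b$t_min | ph$parity > b$t_max)) {
    abort(sprintf("parities outside the basis range [%s, %s] for %s.",
                  b$t_min, b$t_max, spec$trait))
  }
  if (anyDuplicated(ph[c("animal_id", "parity")])) {
    abort("at most one record per animal and parity is allowed.")
  }
  if (spec$service_sire) {
    if (!"service_sire_id" %in% names(ph) || anyNA(ph$service_sire_id)) {
      abort("service-sire effect requested but `service_sire_id` is missing.")
    }
  }
  if (!is.null(relationship)) {
    miss <- setdiff(unique(ph$animal_id), rownames(relationship))
    if (length(miss)) {
      abort(sprintf("relationship matrix lacks %d phenotyped animals (e.g. %s)",
                    length(miss), paste(head(miss, 5), collapse = ", ")))
    }
  }

  ph <- arrange(ph, .data$animal_id, .data$parity)
  pattern_of <- tapply(ph$parity, ph$animal_id,
                       function(t) paste(sort(t), collapse = ","))
  ph$.pattern <- pattern_of[ph$animal_id]
  ph <- arrange(ph, .data$.pattern, .data$animal_id, .data$parity)

  animals <- unique(ph$animal_id)
  n_anim <- length(animals)
  anim_idx <- match(ph$animal_id, animals)

  patterns <- unique(ph$.pattern)
  groups <- lapply(patterns, function(pat) {
    rows <- which(ph$.pattern == pat)
    par <- as.numeric(strsplit(pat, ",")[[1]])
    m <- length(par)
    list(pattern = pat, rows = rows, m = m,
         Phi = eval_basis(b, par),
         animals = match(unique(ph$animal_id[rows]), animals),
         n_g = length(rows) / m)
  })

  fx <- paste(c("1", spec$fixed), collapse = " + ")
  X <- model.matrix(stats::as.formula(paste("~", fx)), data = ph)
  phi_rec <- eval_basis(b, ph$parity)
  if (n_coef(b) > 1) {
    X <- cbind(X, phi1 = phi_rec[, 2])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  sire_levels <- NULL
  sire_idx <- NULL
  if (spec$service_sire) {
    sire_levels <- sort(unique(ph$service_sire_id))
    sire_idx <- match(ph$service_sire_id, sire_levels)
  }

  max_rec <- max(vapply(groups, `[[`, 1, "m"))
  if (max_rec == 1 && spec$include_pe) {
    warn(paste("no animal has more than one record; slope and",
               "permanent-environment components are weakly identifiable."))
  }

  list(y = ph$value, X = X, rec = ph, animals = animals, n_anim = n_anim,
       anim_idx = anim_idx, groups = groups, phi_rec = phi_rec,
       sire_levels = sire_levels, sire_idx = sire_idx,
       basis = b, nc = n_coef(b), n_rec = nrow(ph))
}
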