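#' HPLC pigment profile table
#'
#' Per-replicate pigment masses from HPLC quantification of pooled
#' specimen extracts. Each replicate is one extract of `n_specimens`
#' pooled cells; masses are in ng per extract (`basis = "per_extract"`) or
#' ng per cell (`basis = "per_cell"`). Recognised pigment keys include
#' `chl_a`, `chl_c`, `fuco`, `dd` (diadinoxanthin), `dt` (diatoxanthin),
#' `phaeophytins`, `fuco_like_1`, `fuco_like_2`.
#'
#' @param df data frame with columns `replicate`, `species`,
#'   `n_specimens`, `pigment`, `mass_ng` (long/tidy layout).
#' @param basis `"per_extract"` or `"per_cell"`.
#' @return Object of class `pigment_profile` (the validated data frame
#'   with a `basis` attribute).
#' @export
pigment_profile <- function(df, basis = c("per_extract", "per_cell")) {
  basis <- match.arg(basis)
  need <- c("replicate", "species", "n_specimens", "pigment", "mass_ng")
  if (!all(need %in% names(df)))
    stop("pigment table needs columns: ", paste(need, collapse = ", "))
  if (any(df$mass_ng < 0, na.rm = TRUE)) stop("negative pigment mass")
  if (any(df$n_specimens < 1)) stop("n_specimens must be >= 1")
  structure(as.data.frame(df), basis = basis,
            class = c("pigment_profile", "data.frame"))
}

pigment_basis <- function(profile) attr(profile, "basis")

#' Convert extract masses to per-cell contents
#'
#' Divides every mass by the number of pooled specimens in its replicate,
#' flipping the basis flag to `"per_cell"`. Re-application to an already
#' per-cell table is rejected (the flag makes the operation safe, not
#' idempotent).
#'
#' @param profile `pigment_profile` with basis `"per_extract"`.
#' @return `pigment_profile` with basis `"per_cell"`, masses in ng cell^-1.
#' @export
per_cell <- function(profile) {
  if (!inherits(profile, "pigment_profile"))
    stop("`profile` is not a pigment_profile")
  if (pigment_basis(profile) != "per_extract")
    stop("profile is already on a per-cell basis")
  out <- profile
  out$mass_ng <- out$mass_ng / out$n_specimens
  attr(out, "basis") <- "per_cell"
  out
}

#' Total degradation-pigment content
#'
#' Sum of the degradation-product pigments per replicate (ng cell^-1).
#' Default membership: phaeophytins plus the two fucoxanthin-like
#' degradation products; the list is configurable because which
#' chromatogram peaks count as degradation products is an analytical
#' choice.
#'
#' @param profile per-cell `pigment_profile`.
#' @param members pigment keys counted as degradation products.
#' @return Data frame `replicate`, `species`, `deg_pig`.
#' @export
deg_pig <- function(profile,
                    members = c("phaeophytins", "fuco_like_1",
                                "fuco_like_2")) {
  if (pigment_basis(profile) != "per_cell")
    stop("deg_pig requires a per-cell profile")
  sub <- profile[profile$pigment %in% members, , drop = FALSE]
  keys <- unique(profile[, c("replicate", "species")])
  if (nrow(sub) == 0L) {
    out <- keys
    out$deg_pig <- 0
    return(out[order(out$species, out$replicate), ])
  }
  out <- merge(keys,
               stats::aggregate(mass_ng ~ replicate + species, data = sub,
                                FUN = sum),
               by = c("replicate", "species"), all.x = TRUE)
  out$mass_ng[is.na(out$mass_ng)] <- 0
  names(out)[names(out) == "mass_ng"] <- "deg_pig"
  out[order(out$species, out$replicate), ]
}

#' Pigment ratio indices
#'
#' The ratio block of a per-cell pigment table: Chl c/Chl a, Fuco/Chl a,
#' DT/DD, the xanthophyll de-epoxidation state DT/(DT+DD), the
#' xanthophyll-cycle pool normalised to chlorophyll (DT+DD)/Chl a, and
#' degradation products relative to Chl a. Ratios are computed per
#' replicate; pass a single-row summary (e.g. group means) to get the
#' ratio of means.
#'
#' @param profile per-cell `pigment_profile`.
#' @param deg_members degradation-product membership (see [deg_pig()]).
#' @return Data frame with one row per replicate and columns `replicate`,
#'   `species`, `chlc_chla`, `fuco_chla`, `dt_dd`, `deps`, `xcp_chla`,
#'   `deg_chla`, `deg_pig`.
#' @export
pigment_indices <- function(profile,
                            deg_members = c("phaeophytins", "fuco_like_1",
                                            "fuco_like_2")) {
  if (!inherits(profile, "pigment_profile"))
    stop("`profile` is not a pigment_profile")
  if (pigment_basis(profile) != "per_cell")
    stop("indices require a per-cell profile (run per_cell() first)")
  wide <- stats::reshape(
    profile[, c("replicate", "species", "pigment", "mass_ng")],
    idvar = c("replicate", "species"), timevar = "pigment",
    direction = "wide")
  names(wide) <- sub("^mass_ng\\.", "", names(wide))
  get_col <- function(nm) if (nm %in% names(wide)) wide[[nm]] else
    rep(0, nrow(wide))
  chla <- get_col("chl_a")
  if (any(is.na(chla) | chla <= 0))
    stop("chl_a must be present and > 0 in every replicate")
  dd <- get_col("dd"); dt <- get_col("dt")
  dg <- deg_pig(profile, deg_members)
  dg <- dg[match(paste(wide$replicate, wide$species),
                 paste(dg$replicate, dg$species)), "deg_pig"]
  pool <- dd + dt
  data.frame(
    replicate = wide$replicate, species = wide$species,
    chlc_chla = get_col("chl_c") / chla,
    fuco_chla = get_col("fuco") / chla,
    dt_dd = ifelse(dd > 0, dt / dd, NA_real_),
    deps = ifelse(pool > 0, dt / pool, NA_real_),
    xcp_chla = pool / chla,
    deg_chla = dg / chla,
    deg_pig = dg,
    stringsAsFactors = FALSE)
}

#' Compare pigment indices between species groups
#'
#' Per index, a two-sided Wilcoxon rank-sum test (exact for small n)
#' between the two species' replicate values, flagged at the chosen level.
#'
#' @param indices data frame from [pigment_indices()] covering exactly two
#'   species with >= 2 replicates each.
#' @param alpha significance level (default 0.05).
#' @return Data frame `index`, `p.value`, `significant`.
#' @export
compare_pigment_groups <- function(indices, alpha = 0.05) {
  sp <- unique(indices$species)
  if (length(sp) != 2L) stop("need exactly 2 species groups")
  cols <- setdiff(names(indices), c("replicate", "species"))
  rows <- lapply(cols, function(cn) {
    x <- indices[indices$species == sp[1], cn]
    y <- indices[indices$species == sp[2], cn]
    if (sum(!is.na(x)) < 2L || sum(!is.na(y)) < 2L)
      stop("need >= 2 replicates per group for index ", cn)
    rep <- wilcoxon_ranksum(x, y)
    data.frame(index = cn, p.value = rep$p.value,
               significant = rep$p.value < alpha)
  })
  do.call(rbind, rows)
}
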