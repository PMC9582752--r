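#' Subsite binding profile for a 4-alpha-glucanotransferase
#'
#' A subsite profile holds nonnegative binding affinities for the nine
#' modelled subsites (-6..-1 on the donor side, +1..+3 on the acceptor
#' side; the scissile bond lies between -1 and +1) plus the rate constants
#' of the catalytic cycle: cleavage of a productively bound chain, transfer
#' of the enzyme-held donor fragment to a glucan acceptor, and hydrolysis
#' (transfer to water).
#'
#' Two presets encode the qualitative families: `"GH57_PSGT"` has strong
#' acceptor subsites +1/+2/+3 and permissive donor subsites (a
#' transfer-dominant transglycosylase that releases long fragments and
#' little glucose), while `"GH77_contrast"` has steric hindrance at +2
#' (affinity 0) and a strong donor side, so cleavage releases glucose from
#' the +1 subsite.
#'
#' @param preset `"GH57_PSGT"`, `"GH77_contrast"` or `"custom"`.
#' @param affinities Optional named numeric vector overriding per-subsite
#'   weights; names are subsite indices `"-6"`..`"-1"`, `"1"`..`"3"`.
#' @param cleavage_rate Rate constant of cleavage flux per unit substrate
#'   per unit register weight, min^-1 (mM basis).
#' @param hydrolysis_rate Rate constant for water as acceptor, min^-1.
#' @param transfer_rate Rate constant for glucan acceptors, min^-1 mM^-1.
#' @param plus_overhang Maximum chain units allowed to overhang past +3 in
#'   a productive placement (default 1).
#' @param max_length Longest tracked glucan, glucose units (default 20).
#' @param max_pnp_length Longest tracked pNP-labelled species (default 12).
#' @return An object of class `subsite_profile`.
#' @export
subsite_profile <- function(preset = c("GH57_PSGT", "GH77_contrast", "custom"),
                            affinities = NULL,
                            cleavage_rate = 0.003,
                            hydrolysis_rate = 0.05,
                            transfer_rate = 1,
                            plus_overhang = 1L,
                            max_length = 20L,
                            max_pnp_length = 12L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    GH57_PSGT = c("-6" = 0.3, "-5" = 0.3, "-4" = 0.3, "-3" = 0.3, "-2" = 0.3,
                  "-1" = 1, "1" = 3, "2" = 3, "3" = 3),
    GH77_contrast = c("-6" = 0.3, "-5" = 0.3, "-4" = 1, "-3" = 3, "-2" = 3,
                      "-1" = 3, "1" = 1, "2" = 0, "3" = 0),
    custom = c("-6" = 1, "-5" = 1, "-4" = 1, "-3" = 1, "-2" = 1,
               "-1" = 1, "1" = 1, "2" = 1, "3" = 1)
  )
  if (!is.null(affinities)) {
    bad <- setdiff(names(affinities), names(base))
    if (length(bad)) {
      stop_gt(sprintf("Unknown subsite(s) in affinities: %s", paste(bad, collapse = ", ")),
              "gt_validation_error")
    }
    base[names(affinities)] <- affinities
  }
  if (any(!is.finite(base)) || any(base < 0)) {
    stop_gt("Subsite affinities must be finite and >= 0.", "gt_validation_error")
  }
  if (base[["-1"]] <= 0 || base[["1"]] <= 0) {
    stop_gt("Subsites -1 and +1 must have affinity > 0.", "gt_validation_error")
  }
  for (r in c(cleavage_rate, hydrolysis_rate, transfer_rate)) {
    if (!is.finite(r) || r < 0) {
      stop_gt("Rate constants must be finite and >= 0.", "gt_validation_error")
    }
  }
  structure(list(name = preset, affinities = base,
                 cleavage_rate = cleavage_rate,
                 hydrolysis_rate = hydrolysis_rate,
                 transfer_rate = transfer_rate,
                 plus_overhang = as.integer(plus_overhang),
                 max_length = as.integer(max_length),
                 max_pnp_length = as.integer(max_pnp_length)),
            class = "subsite_profile")
}

#' @export
print.subsite_profile <- function(x, ...) {
  cat(sprintf("Subsite profile '%s'\n", x$name))
  cat("  affinities:", paste(sprintf("%s:%g", fmt_subsite(names(x$affinities)),
                                     x$affinities), collapse = " "), "\n")
  cat(sprintf("  cleavage %g, transfer %g, hydrolysis %g; +overhang <= %d\n",
              x$cleavage_rate, x$transfer_rate, x$hydrolysis_rate, x$plus_overhang))
  invisible(x)
}

# linear slot <-> subsite code; slots 1..9 are -6..-1,+1..+3, no slot 0 subsite
slot_to_subsite <- function(l) ifelse(l <= 6, l - 7L, l - 6L)

# species labels: "G5", "pNPG6"
species_name <- function(length, label = "none") {
  paste0(if (identical(label, "pNP")) "pNPG" else "G", length)
}

parse_species <- function(name) {
  if (grepl("^pNPG[0-9]+$", name)) {
    list(length = as.integer(sub("^pNPG", "", name)), label = "pNP")
  } else if (grepl("^G[0-9]+$", name)) {
    list(length = as.integer(sub("^G", "", name)), label = "none")
  } else {
    stop_gt(sprintf("Unrecognised species name '%s' (expected Gn or pNPGn).", name),
            "gt_validation_error")
  }
}

#' Enumerate binding registers of a glucan chain on the subsite array
#'
#' All contiguous placements of the chain on the nine modelled subsites are
#' listed, with the non-reducing end toward the negative (donor) subsites.
#' A pNP label occupies the slot distal of the reducing-end glucose.
#' Placements fully inside the array are always enumerated; placements that
#' overhang past +3 (at most `plus_overhang` units) are enumerated only
#' when productive, and overhang past -6 only when the chain is longer than
#' the array. Overhanging units contribute neutral weight. A placement is
#' productive when glucose units occupy both -1 and +1, the positions
#' flanking the scissile bond.
#'
#' @param length Chain length, glucose units (>= 1).
#' @param profile A [subsite_profile()].
#' @param label `"none"` or `"pNP"` (reducing-end label).
#' @return Tibble with one row per register: `start_subsite`, `occupied`
#'   (list of subsite codes), `productive`, `weight`, and for productive
#'   rows `donor_length`, `released_length`, `released_label`.
#' @export
enumerate_registers <- function(length, profile, label = c("none", "pNP")) {
  label <- match.arg(label)
  if (length < 1) stop_gt("Chain length must be >= 1.", "gt_validation_error")
  l_eff <- length + (label == "pNP")
  minus_cap <- max(0L, l_eff - 9L)
  plus_cap <- profile$plus_overhang
  starts <- seq.int(1L - minus_cap, 9L - l_eff + 1L + plus_cap)
  rows <- purrr::map(starts, function(s) {
    occ <- s:(s + l_eff - 1L)
    om <- max(0L, 1L - s)
    op <- max(0L, s + l_eff - 1L - 9L)
    if (om > minus_cap || op > plus_cap) return(NULL)
    covers <- all(c(6L, 7L) %in% occ)
    # the unit on +1 must be a glucose (the pNP group sits most-positive)
    productive <- covers && (8L - s) <= length
    if ((om + op) > 0L && !productive) return(NULL)
    inside <- occ[occ >= 1L & occ <= 9L]
    w <- prod(profile$affinities[as.character(slot_to_subsite(inside))])
    donor <- sum(occ <= 6L)
    tibble::tibble(
      start_subsite = slot_to_subsite(s),
      occupied = list(slot_to_subsite(occ)),
      productive = productive,
      weight = unname(w),
      donor_length = if (productive) donor else NA_integer_,
      released_length = if (productive) l_eff - donor - (label == "pNP") else NA_integer_,
      released_label = if (productive) label else NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

#' Binding weight of one register
#'
#' Product of per-subsite affinities over the occupied subsites; units
#' overhanging the modelled array contribute a neutral factor of 1.
#'
#' @param occupied Integer vector of occupied subsite codes (no 0; codes
#'   outside -6..+3 are overhang).
#' @param profile A [subsite_profile()].
#' @return Nonnegative weight.
#' @export
register_weight <- function(occupied, profile) {
  inside <- occupied[occupied >= -6 & occupied <= 3 & occupied != 0]
  prod(profile$affinities[as.character(inside)])
}

#' Reaction state of the disproportionation system
#'
#' @param amounts Named numeric vector of free species amounts (names
#'   `"Gn"` / `"pNPGn"`), mM for the deterministic engine or molecule
#'   counts for the stochastic engine.
#' @param intermediates Named numeric vector of enzyme-held donor-fragment
#'   amounts, names `"Gn"` by fragment length (default none).
#' @param time Reaction time, minutes.
#' @return An object of class `reaction_state`.
#' @export
reaction_state <- function(amounts, intermediates = NULL, time = 0) {
  if (is.data.frame(amounts)) {
    amounts <- stats::setNames(amounts$amount, amounts$species)
  }
  if (is.null(names(amounts)) || any(!nzchar(names(amounts)))) {
    stop_gt("Species amounts must be named (e.g. c(G5 = 10)).", "gt_validation_error")
  }
  purrr::walk(names(amounts), parse_species)
  if (any(amounts < 0)) stop_gt("Amounts must be >= 0.", "gt_validation_error")
  intermediates <- intermediates %||% stats::setNames(numeric(0), character(0))
  if (length(intermediates)) {
    purrr::walk(names(intermediates), parse_species)
    if (any(intermediates < 0)) stop_gt("Amounts must be >= 0.", "gt_validation_error")
  }
  structure(list(amounts = amounts, intermediates = intermediates, time = time),
            class = "reaction_state")
}

#' Total glucose units held in a reaction state
#'
#' Free species plus enzyme-held fragments; conserved by every reaction of
#' the model.
#'
#' @param state A [reaction_state()].
#' @return Total glucose-unit quantity.
#' @export
glucan_units <- function(state) {
  len <- function(v) vapply(names(v), function(nm) parse_species(nm)$length, integer(1))
  tot <- 0
  if (length(state$amounts)) tot <- tot + sum(len(state$amounts) * state$amounts)
  if (length(state$intermediates)) {
    tot <- tot + sum(len(state$intermediates) * state$intermediates)
  }
  tot
}

add_amount <- function(v, name, q) {
  v[name] <- (if (name %in% names(v)) v[[name]] else 0) + q
  if (v[[name]] < -1e-12) {
    stop_gt(sprintf("Amount of %s would become negative.", name), "gt_validation_error")
  }
  v[name] <- max(v[[name]], 0)
  v
}

#' Cleave a productively bound chain and partition the fragments
#'
#' Applies one cleavage event: the bond between the units at -1 and +1 is
#' broken, the acceptor-side fragment (units on +1 and beyond, carrying the
#' pNP label when present) is released to solution, and the donor-side
#' fragment becomes a covalent enzyme-held intermediate, later resolved by
#' [transfer_intermediate()] or [hydrolyze_intermediate()]. A nonproductive
#' register is a no-op (with a warning).
#'
#' @param state A [reaction_state()].
#' @param species Species name being cleaved (e.g. `"G5"`).
#' @param register One row of [enumerate_registers()] for that species.
#' @param quantity Amount converted (default 1).
#' @return The updated `reaction_state`.
#' @export
cleave_and_partition <- function(state, species, register, quantity = 1) {
  if (!isTRUE(register$productive[1])) {
    warning("Nonproductive register: no cleavage performed.", call. = FALSE)
    return(state)
  }
  rel <- species_name(register$released_length[1], register$released_label[1])
  donor <- species_name(register$donor_length[1])
  state$amounts <- add_amount(state$amounts, species, -quantity)
  state$amounts <- add_amount(state$amounts, rel, quantity)
  state$intermediates <- add_amount(state$intermediates, donor, quantity)
  state
}

#' Resolve an enzyme-held fragment by transfer to a glucan acceptor
#'
#' The donor fragment is concatenated onto the non-reducing end of the
#' acceptor: the product length is donor + acceptor and the product keeps
#' the acceptor's label. Products beyond the profile's length cap are
#' truncated into the cap bin (with a warning).
#'
#' @param state A [reaction_state()].
#' @param donor_length Enzyme-held fragment length, glucose units.
#' @param acceptor Acceptor species name.
#' @param profile A [subsite_profile()] (length caps).
#' @param quantity Amount transferred (default 1).
#' @return The updated `reaction_state`.
#' @export
transfer_intermediate <- function(state, donor_length, acceptor, profile,
                                  quantity = 1) {
  acc <- parse_species(acceptor)
  cap <- if (acc$label == "pNP") profile$max_pnp_length else profile$max_length
  new_len <- donor_length + acc$length
  if (new_len > cap) {
    warning(sprintf("Transfer product G%d exceeds the length cap; truncated to %d units.",
                    new_len, cap), call. = FALSE)
    new_len <- cap
  }
  donor <- species_name(donor_length)
  state$intermediates <- add_amount(state$intermediates, donor, -quantity)
  state$amounts <- add_amount(state$amounts, acceptor, -quantity)
  state$amounts <- add_amount(state$amounts, species_name(new_len, acc$label), quantity)
  state
}

#' Resolve an enzyme-held fragment by hydrolysis (water as acceptor)
#'
#' @param state A [reaction_state()].
#' @param donor_length Enzyme-held fragment length.
#' @param quantity Amount hydrolysed (default 1).
#' @return The updated `reaction_state`.
#' @export
hydrolyze_intermediate <- function(state, donor_length, quantity = 1) {
  donor <- species_name(donor_length)
  state$intermediates <- add_amount(state$intermediates, donor, -quantity)
  state$amounts <- add_amount(state$amounts, donor, quantity)
  state
}

# acceptor binding weight: product of +1..+3 affinities covered by the
# acceptor chain (pNP slot included); units past +3 contribute 1
acceptor_weight <- function(length, label, profile) {
  l_eff <- length + (label == "pNP")
  inside <- seq_len(min(l_eff, 3L))
  prod(profile$affinities[as.character(inside)])
}
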