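#' Define a cleavable cross-linker chemistry
#'
#' A cross-linker definition carries the stub fragments left on each peptide
#' after gas-phase cleavage, the doublet pairs used for matching, and the
#' intact linker residual mass. Stub masses may be given as elemental
#' compositions (preferred: a single atomic-mass table then governs all
#' arithmetic) or as literal masses.
#'
#' @param name linker name.
#' @param stubs data frame with columns `label` and either `composition`
#'   or `mass` (Da). Labels must be unique, masses strictly positive.
#' @param doublet_pairs data frame with columns `light`, `heavy` (stub
#'   labels) and optionally `active` (logical; defaults to TRUE). The heavy
#'   stub must be heavier than the light one.
#' @param full_mass intact linker residual mass in Da; if `NULL`, the sum of
#'   the lightest and heaviest stub masses is used (valid for symmetric
#'   sulfoxide linkers like DSSO where cleavage conserves the linker as
#'   alkene + sulfenic acid).
#' @return a list of class `crosslinker` with elements `name`, `full_mass`,
#'   `stubs` (tibble: label, mass), `doublet_pairs` (tibble: light, heavy,
#'   delta_mass, active).
#' @seealso [dsso()] for the built-in DSSO definition.
#' @export
crosslinker <- function(name, stubs, doublet_pairs, full_mass = NULL) {
  stubs <- tibble::as_tibble(stubs)
  if (!"mass" %in% names(stubs)) {
    if (!"composition" %in% names(stubs)) {
      stop("stubs need a 'composition' or 'mass' column", call. = FALSE)
    }
    stubs$mass <- composition_mass(stubs$composition)
  }
  if (anyDuplicated(stubs$label)) stop("duplicate stub labels", call. = FALSE)
  if (any(stubs$mass <= 0)) stop("stub masses must be > 0", call. = FALSE)

  doublet_pairs <- tibble::as_tibble(doublet_pairs)
  if (!"active" %in% names(doublet_pairs)) doublet_pairs$active <- TRUE
  unknown <- setdiff(c(doublet_pairs$light, doublet_pairs$heavy), stubs$label)
  if (length(unknown)) {
    stop("doublet pair references unknown stub(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mass_of <- function(lbl) stubs$mass[match(lbl, stubs$label)]
  doublet_pairs$delta_mass <- mass_of(doublet_pairs$heavy) - mass_of(doublet_pairs$light)
  if (any(doublet_pairs$delta_mass <= 0)) {
    stop("doublet pairs must have heavy.mass > light.mass", call. = FALSE)
  }
  if (is.null(full_mass)) {
    full_mass <- min(stubs$mass) + max(stubs$mass)
  }
  if (any(mass_of(doublet_pairs$light) > full_mass)) {
    stop("stub mass exceeds full linker mass", call. = FALSE)
  }
  structure(
    list(name = name, full_mass = full_mass,
         stubs = stubs[, c("label", "mass")],
         doublet_pairs = doublet_pairs[, c("light", "heavy", "delta_mass", "active")]),
    class = "crosslinker"
  )
}

#' @export
print.crosslinker <- function(x, ...) {
  cat("<crosslinker>", x$name, " full mass", format(x$full_mass, digits = 9), "Da\n")
  print(x$stubs)
  print(x$doublet_pairs)
  invisible(x)
}

#' The DSSO cross-linker
#'
#' Disuccinimidyl sulfoxide (DSSO) cleaves asymmetrically at either C-S bond
#' flanking the central sulfoxide, leaving an alkene stub (A, C3H2O) on one
#' peptide and a sulfenic-acid stub (S, C3H4O2S) on the other; sulfenic acid
#' readily loses water to the thiol stub (T, C3H2OS). Doublet matching uses
#' the A/T pair by default (delta = one sulfur atom, ~31.9721 Da); the A/S
#' pair is defined but inactive. The intact linker residual mass is
#' mass(A) + mass(S), since a single cleavage conserves the linker.
#'
#' All masses are derived from elemental compositions at construction time.
#'
#' @return a `crosslinker` object.
#' @examples
#' xl <- dsso()
#' xl$doublet_pairs
#' @export
dsso <- function() {
  crosslinker(
    name = "DSSO",
    stubs = tibble::tibble(
      label = c("A", "S", "T"),
      composition = c("C3H2O", "C3H4O2S", "C3H2OS")
    ),
    doublet_pairs = tibble::tibble(
      light = c("A", "A"), heavy = c("T", "S"),
      active = c(TRUE, FALSE)
    ),
    full_mass = composition_mass("C3H2O") + composition_mass("C3H4O2S")
  )
}

#' Load a cross-linker definition from a config file or list
#'
#' Accepts a YAML file path or an already-parsed list with fields `name`,
#' `stubs` (each with `label` and `composition` or `mass`), `doublet_pairs`
#' (each with `light`, `heavy`, optional `active`) and optional `full_mass`.
#' The shortcut string `"dsso"` returns [dsso()].
#'
#' @param config path to a YAML file, a list, or `"dsso"`.
#' @return a validated `crosslinker` object.
#' @export
load_crosslinker <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (tolower(config) == "dsso") return(dsso())
    config <- yaml::read_yaml(config)
    if (!is.null(config$crosslinker)) config <- config$crosslinker
  }
  stopifnot(is.list(config))
  stubs <- dplyr::bind_rows(lapply(config$stubs, tibble::as_tibble))
  pairs <- dplyr::bind_rows(lapply(config$doublet_pairs, tibble::as_tibble))
  crosslinker(name = config$name %||% "custom", stubs = stubs,
              doublet_pairs = pairs, full_mass = config$full_mass)
}

active_pairs <- function(xl) {
  p <- xl$doublet_pairs[xl$doublet_pairs$active, , drop = FALSE]
  mass_of <- function(lbl) xl$stubs$mass[match(lbl, xl$stubs$label)]
  p$light_mass <- mass_of(p$light)
  p$heavy_mass <- mass_of(p$heavy)
  p
}
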