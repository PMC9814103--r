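# Mixed continuous/categorical design space: declaration, encoding to the
# unit-cube + one-hot representation used by the surrogate, decoding with
# nearest-vertex rounding, lab-grid snapping, and residence-time arithmetic.

#' Declare a continuous reaction parameter
#'
#' @param name identifier, unique within a space.
#' @param low,high inclusive bounds in native units (`low < high`).
#' @param units free-text unit label (e.g. `"degC"`, `"mol%"`, `"M"`,
#'   `"mL/min"`, `"equiv"`). Informational only.
#' @param precision lab-resolution grid step used when snapping proposals to
#'   experimentally settable values (e.g. 0.1 equiv, 5 degC). Must satisfy
#'   `0 < precision <= high - low`.
#' @return an object of class `flowbo_param` (type `"continuous"`).
#' @seealso [categorical_param()], [parameter_space()]
#' @export
continuous_param <- function(name, low, high, units = "", precision) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("parameter name must be a non-empty string")
  low <- as.numeric(low); high <- as.numeric(high)
  precision <- as.numeric(precision)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stopf("parameter '%s': need finite low < high (got %g, %g)", name, low, high)
  if (!is.finite(precision) || precision <= 0 || precision > high - low)
    stopf("parameter '%s': precision must be in (0, high - low]", name)
  structure(
    list(name = name, type = "continuous", low = low, high = high,
         units = units, precision = precision),
    class = "flowbo_param"
  )
}

#' Declare a categorical reaction parameter
#'
#' The order of `choices` is fixed and defines the one-hot column order in the
#' encoded representation.
#'
#' @param name identifier, unique within a space.
#' @param choices character vector of at least two distinct labels.
#' @return an object of class `flowbo_param` (type `"categorical"`).
#' @export
categorical_param <- function(name, choices) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("parameter name must be a non-empty string")
  choices <- as.character(choices)
  if (length(choices) < 2L || anyDuplicated(choices))
    stopf("parameter '%s': need >= 2 distinct choice labels", name)
  structure(
    list(name = name, type = "categorical", choices = choices),
    class = "flowbo_param"
  )
}

#' Assemble a mixed design space
#'
#' Builds the ordered design space over which conditions are encoded for the
#' Gaussian-process surrogate. The encoded layout is deterministic: all
#' continuous parameters first (declaration order), each min-max scaled to
#' \[0, 1\], followed by one one-hot block per categorical parameter
#' (declaration order, block columns in choice order).
#'
#' @param params list of [continuous_param()] / [categorical_param()] objects.
#' @param mixers optional list of [mixer_spec()] objects attached to the space
#'   so that residence times can be derived for proposals.
#' @return an object of class `flowbo_space` with fields `params`, `mixers`,
#'   `encoded_dim` and the internal column `layout`.
#' @export
parameter_space <- function(params, mixers = NULL) {
  if (length(params) == 0L) stopf("a parameter space needs at least one parameter")
  nm <- vapply(params, function(p) p$name, "")
  if (anyDuplicated(nm)) stopf("duplicate parameter name '%s'", nm[duplicated(nm)][1L])
  types <- vapply(params, function(p) p$type, "")
  cont <- params[types == "continuous"]
  cats <- params[types == "categorical"]
  layout <- list()
  col <- 0L
  for (p in cont) {
    layout[[p$name]] <- list(type = "continuous", cols = col + 1L)
    col <- col + 1L
  }
  for (p in cats) {
    k <- length(p$choices)
    layout[[p$name]] <- list(type = "categorical", cols = col + seq_len(k))
    col <- col + k
  }
  if (!is.null(mixers)) {
    mn <- vapply(mixers, function(m) m$name, "")
    if (anyDuplicated(mn)) stopf("duplicate mixer name '%s'", mn[duplicated(mn)][1L])
  }
  structure(
    list(params = params, mixers = mixers, encoded_dim = col, layout = layout),
    class = "flowbo_space"
  )
}

#' @export
print.flowbo_space <- function(x, ...) {
  cat(sprintf("<flowbo_space> %d parameters, encoded_dim = %d\n",
              length(x$params), x$encoded_dim))
  for (p in x$params) {
    if (p$type == "continuous") {
      cat(sprintf("  %-14s continuous  [%g, %g] %s (precision %g)\n",
                  p$name, p$low, p$high, p$units, p$precision))
    } else {
      cat(sprintf("  %-14s categorical {%s}\n", p$name,
                  paste(p$choices, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Number of encoded dimensions of a space
#' @param space a `flowbo_space`.
#' @return integer: number of continuous parameters plus the total number of
#'   categorical choices.
#' @export
encoded_dim <- function(space) space$encoded_dim

param_names <- function(space) vapply(space$params, function(p) p$name, "")

get_param <- function(space, name) {
  for (p in space$params) if (p$name == name) return(p)
  stopf("unknown parameter '%s'", name)
}

#' Validate a condition against a space
#'
#' A condition is a named list (or one-row data.frame) assigning every
#' parameter of the space exactly one value: a numeric within bounds for
#' continuous parameters, a known choice label for categorical ones.
#'
#' @param space a `flowbo_space`.
#' @param cond named list or one-row data.frame of assignments.
#' @return the condition as a named list, invisibly standardized; errors name
#'   the offending field.
#' @export
validate_condition <- function(space, cond) {
  if (is.data.frame(cond)) {
    if (nrow(cond) != 1L) stopf("condition data.frame must have exactly one row")
    cond <- as.list(cond)
  }
  nm <- param_names(space)
  missing <- setdiff(nm, names(cond))
  if (length(missing))
    stopf("condition is missing parameter '%s'", missing[1L])
  out <- vector("list", length(nm)); names(out) <- nm
  for (p in space$params) {
    v <- cond[[p$name]]
    if (length(v) != 1L) stopf("parameter '%s': expected a single value", p$name)
    if (p$type == "continuous") {
      v <- suppressWarnings(as.numeric(v))
      if (!is.finite(v))
        stopf("parameter '%s': non-numeric or non-finite value", p$name)
      tol <- 1e-9 * max(1, abs(p$high - p$low))
      if (v < p$low - tol || v > p$high + tol)
        stopf("parameter '%s': value %g outside bounds [%g, %g]",
              p$name, v, p$low, p$high)
      out[[p$name]] <- min(max(v, p$low), p$high)
    } else {
      v <- as.character(v)
      if (!v %in% p$choices)
        stopf("parameter '%s': unknown label '%s' (choices: %s)",
              p$name, v, paste(p$choices, collapse = ", "))
      out[[p$name]] <- v
    }
  }
  out
}

#' Encode a condition to the unit-cube / one-hot representation
#'
#' Continuous values map to `(v - low) / (high - low)`; each categorical label
#' maps to its one-hot block (a single 1 at the choice index). The result is a
#' non-relaxed encoded vector: every one-hot block is an exact vertex.
#'
#' @param space a `flowbo_space`.
#' @param cond a valid condition (see [validate_condition()]).
#' @return numeric vector of length `encoded_dim(space)`.
#' @export
encode_condition <- function(space, cond) {
  cond <- validate_condition(space, cond)
  v <- numeric(space$encoded_dim)
  for (p in space$params) {
    cols <- space$layout[[p$name]]$cols
    if (p$type == "continuous") {
      v[cols] <- (cond[[p$name]] - p$low) / (p$high - p$low)
    } else {
      block <- numeric(length(p$choices))
      block[match(cond[[p$name]], p$choices)] <- 1
      v[cols] <- block
    }
  }
  v
}

#' Encode several conditions as a matrix
#'
#' @param space a `flowbo_space`.
#' @param conds list of conditions, or a data.frame with one column per
#'   parameter and one row per condition.
#' @return numeric matrix, one encoded row per condition.
#' @export
encode_conditions <- function(space, conds) {
  if (is.data.frame(conds)) {
    conds <- lapply(seq_len(nrow(conds)), function(i)
      as.list(conds[i, param_names(space), drop = FALSE]))
  }
  X <- t(vapply(conds, function(cc) encode_condition(space, cc),
                numeric(space$encoded_dim)))
  if (space$encoded_dim == 1L) X <- matrix(X, ncol = 1L)
  X
}

#' Decode an encoded (possibly relaxed) vector to a condition
#'
#' Continuous dimensions are clipped to \[0, 1\] and unscaled to native
#' units. Each one-hot block is decoded by the largest-component rule
#' (nearest vertex); ties break to the lowest choice index. For any valid
#' condition `decode(encode(c))` returns `c` up to floating tolerance.
#'
#' @param space a `flowbo_space`.
#' @param vec numeric vector of length `encoded_dim(space)`.
#' @return a condition (named list).
#' @export
decode_vector <- function(space, vec) {
  if (length(vec) != space$encoded_dim)
    stopf("encoded vector has length %d, expected %d",
          length(vec), space$encoded_dim)
  if (any(!is.finite(vec))) stopf("encoded vector contains non-finite values")
  out <- list()
  for (p in space$params) {
    cols <- space$layout[[p$name]]$cols
    if (p$type == "continuous") {
      u <- min(max(vec[cols], 0), 1)
      out[[p$name]] <- p$low + u * (p$high - p$low)
    } else {
      out[[p$name]] <- p$choices[which.max(vec[cols])]
    }
  }
  out
}

#' Snap a condition to the laboratory precision grid
#'
#' Each continuous value is rounded to the nearest multiple of its declared
#' `precision`, then clipped into bounds; categorical values are unchanged.
#' Proposals are always snapped so that suggested conditions are settable on
#' real pumps/heaters at the declared resolution.
#'
#' @param space a `flowbo_space`.
#' @param cond a valid condition.
#' @return the snapped condition.
#' @export
snap_to_lab_grid <- function(space, cond) {
  cond <- validate_condition(space, cond)
  for (p in space$params) {
    if (p$type != "continuous") next
    v <- round(cond[[p$name]] / p$precision) * p$precision
    cond[[p$name]] <- min(max(v, p$low), p$high)
  }
  cond
}

# Stable identity key for dedupe of snapped conditions.
condition_key <- function(space, cond) {
  parts <- vapply(space$params, function(p) {
    v <- cond[[p$name]]
    if (p$type == "continuous") sprintf("%.9g", round(v, 9)) else as.character(v)
  }, "")
  paste(parts, collapse = "|")
}

#' Declare a micromixer (reactor) with its internal volume
#'
#' @param name label, e.g. `"comet_x"`.
#' @param volume_mL internal volume in mL, strictly positive.
#' @return an object of class `flowbo_mixer`.
#' @export
mixer_spec <- function(name, volume_mL) {
  volume_mL <- as.numeric(volume_mL)
  if (!is.finite(volume_mL) || volume_mL <= 0)
    stopf("mixer '%s': volume_mL must be > 0", name)
  structure(list(name = as.character(name), volume_mL = volume_mL),
            class = "flowbo_mixer")
}

#' Residence time of a dual-feed flow reactor
#'
#' The reactor is fed by two syringe pumps running at the same per-stream flow
#' rate, so the combined volumetric flow is twice the per-stream rate and the
#' residence time is `volume_mL / (2 * per_stream_flow_mL_min)` minutes.
#'
#' @param mixer a [mixer_spec()].
#' @param per_stream_flow_mL_min flow rate of each individual feed stream in
#'   mL/min, strictly positive.
#' @return residence time in minutes.
#' @examples
#' residence_time(mixer_spec("comet_x", 2.4), 0.08)  # 15 minutes
#' @export
residence_time <- function(mixer, per_stream_flow_mL_min) {
  if (!inherits(mixer, "flowbo_mixer")) stopf("mixer must be a flowbo_mixer")
  f <- as.numeric(per_stream_flow_mL_min)
  if (!is.finite(f) || f <= 0) stopf("flow rate must be > 0 (got %g)", f)
  mixer$volume_mL / (2 * f)
}

lookup_mixer <- function(space, name) {
  for (m in space$mixers %||% list()) if (m$name == name) return(m)
  NULL
}

# ---- configuration files ----------------------------------------------------

space_to_list <- function(space) {
  list(
    parameters = lapply(space$params, function(p) {
      if (p$type == "continuous") {
        list(name = p$name, type = "continuous", low = p$low, high = p$high,
             units = p$units, precision = p$precision)
      } else {
        list(name = p$name, type = "categorical", choices = as.list(p$choices))
      }
    }),
    mixers = lapply(space$mixers %||% list(), function(m)
      list(name = m$name, volume_mL = m$volume_mL))
  )
}

space_from_list <- function(x) {
  params <- lapply(x$parameters, function(p) {
    type <- p$type %||% stopf("space config entry without 'type'")
    if (type == "continuous") {
      continuous_param(p$name, p$low, p$high, units = p$units %||% "",
                       precision = p$precision %||%
                         stopf("parameter '%s': missing precision", p$name))
    } else if (type == "categorical") {
      categorical_param(p$name, unlist(p$choices))
    } else stopf("parameter '%s': unknown type '%s'", p$name %||% "?", type)
  })
  mixers <- lapply(x$mixers %||% list(), function(m)
    mixer_spec(m$name, m$volume_mL))
  if (length(mixers) == 0L) mixers <- NULL
  parameter_space(params, mixers = mixers)
}

#' Read a design-space configuration file
#'
#' The configuration is YAML (JSON also parses) with a `parameters` list --
#' each entry carrying `name`, `type: continuous|categorical` and either
#' `low/high/units/precision` or `choices` -- and an optional `mixers` list of
#' `name`/`volume_mL` pairs. Two configs ship with the package:
#' `space_screening.yaml` (the announced screening ranges) and
#' `space_widened.yaml` (bounds widened to cover every condition appearing in
#' the packaged campaigns).
#'
#' @param path path to a YAML/JSON config file.
#' @return a `flowbo_space`.
#' @export
read_space_config <- function(path) {
  if (!file.exists(path)) stopf("space config not found: %s", path)
  space_from_list(yaml::read_yaml(path))
}

#' The six-parameter flow biaryl screening space
#'
#' Five continuous parameters (arenol equivalents, TfOH catalyst loading,
#' temperature, substrate concentration, per-stream flow rate) and one
#' categorical parameter (micromixer type: Comet X, beta-type, T-shaped, with
#' internal volumes 2.4 / 2.7 / 1.6 mL). `default_space()` uses the announced
#' screening ranges; `widened_space()` widens the bounds so that every
#' condition the optimizer suggested during the packaged campaigns --
#' several of which extrapolate beyond the initial ranges -- validates.
#'
#' @return a `flowbo_space`.
#' @export
default_space <- function() {
  parameter_space(
    list(
      categorical_param("mixer", c("comet_x", "beta_type", "t_shaped")),
      continuous_param("equiv",        1,    3,   "equiv",  0.1),
      continuous_param("tfoh_mol_pct", 0.5,  2,   "mol%",   0.01),
      continuous_param("temp_c",       20,   60,  "degC",   5),
      continuous_param("conc_m",       0.01, 0.1, "M",      0.001),
      continuous_param("flow_ml_min",  0.05, 0.2, "mL/min", 0.001)
    ),
    mixers = default_mixers()
  )
}

#' @rdname default_space
#' @export
widened_space <- function() {
  parameter_space(
    list(
      categorical_param("mixer", c("comet_x", "beta_type", "t_shaped")),
      continuous_param("equiv",        1,    3.5,  "equiv",  0.1),
      continuous_param("tfoh_mol_pct", 0.2,  2.5,  "mol%",   0.01),
      continuous_param("temp_c",       15,   85,   "degC",   5),
      continuous_param("conc_m",       0.01, 0.15, "M",      0.001),
      continuous_param("flow_ml_min",  0.014, 0.2, "mL/min", 0.001)
    ),
    mixers = default_mixers()
  )
}

#' @rdname default_space
#' @export
default_mixers <- function() {
  list(
    mixer_spec("comet_x",   2.4),
    mixer_spec("beta_type", 2.7),
    mixer_spec("t_shaped",  1.6)
  )
}

#' Display labels for the packaged mixer names
#'
#' Mixer labels are stored as ASCII snake_case in CSV files and configs
#' (`beta_type` rather than a Greek letter) to keep round-trips
#' encoding-safe; this map recovers the display names.
#'
#' @return named character vector mapping storage labels to display labels.
#' @export
mixer_display_labels <- function() {
  c(comet_x = "Comet X", beta_type = "\u03b2-type", t_shaped = "T-shaped")
}
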