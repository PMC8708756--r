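# L-system grammar, wind modulation and turtle interpretation for wheat stems.
#
# Stems are grown by iterated parallel rewriting of a symbol string; the
# expanded string is interpreted as 3D turtle graphics where "F" draws a
# segment and "+"/"-" pitch the heading toward/away from a horizontal
# azimuth. Wind supplies an additional per-segment pitch schedule whose
# magnitude grows toward the stem tip.

LSYS_ALPHABET <- c("F", "+", "-", "[", "]")

#' L-system specification
#'
#' Defines the string-rewriting grammar and turtle parameters used to grow a
#' wheat stem. The default grammar `F -> "FF+F"` expanded three times gives a
#' 27-segment gently curving stem.
#'
#' @param axiom starting symbol string.
#' @param rules named character vector or list mapping a single symbol to its
#'   replacement string; symbols without a rule map to themselves.
#' @param iterations number of parallel rewriting passes (>= 0).
#' @param step_length world-unit length of one "F" segment.
#' @param base_bend pitch angle in radians applied per "+"/"-" symbol.
#' @return An object of class `lsystem_spec`.
#' @examples
#' spec <- lsystem_spec("A", c(A = "AB", B = "A"), iterations = 5)
#' nchar(expand_lsystem(spec)) # Fibonacci growth: 8
#' @export
lsystem_spec <- function(axiom = "F", rules = c(F = "FF+F"), iterations = 3L,
                         step_length = 0.04, base_bend = 0.035) {
  rules <- as.list(rules)
  if (!is.character(axiom) || length(axiom) != 1L || nchar(axiom) < 1L)
    stopf("axiom must be a non-empty string")
  if (!is_scalar_num(iterations) || iterations < 0)
    stopf("iterations must be a non-negative integer")
  alphabet <- union(LSYS_ALPHABET, names(rules))
  check_symbols <- function(s, what) {
    syms <- strsplit(s, "")[[1]]
    bad <- setdiff(syms, alphabet)
    if (length(bad))
      stopf("%s contains symbols outside the alphabet: %s", what,
            paste(unique(bad), collapse = " "))
  }
  check_symbols(axiom, "axiom")
  for (nm in names(rules)) {
    if (nchar(nm) != 1L) stopf("rule keys must be single symbols (got '%s')", nm)
    check_symbols(rules[[nm]], sprintf("rule for '%s'", nm))
  }
  structure(
    list(axiom = axiom, rules = rules, iterations = as.integer(iterations),
         step_length = step_length, base_bend = base_bend,
         alphabet = alphabet),
    class = "lsystem_spec")
}

#' Expand an L-system to its symbol string
#'
#' Applies the rule map simultaneously to every symbol of the current string,
#' `iterations` times. Symbols without a rule are copied unchanged.
#'
#' @param spec an [lsystem_spec()].
#' @return The expanded symbol string.
#' @export
expand_lsystem <- function(spec) {
  stopifnot(inherits(spec, "lsystem_spec"))
  s <- spec$axiom
  if (spec$iterations == 0L) return(s)
  rules <- spec$rules
  for (i in seq_len(spec$iterations)) {
    syms <- strsplit(s, "")[[1]]
    out <- vapply(syms, function(sym) {
      r <- rules[[sym]]
      if (is.null(r)) sym else r
    }, character(1), USE.NAMES = FALSE)
    s <- paste0(out, collapse = "")
  }
  s
}

#' Wind state
#'
#' @param speed non-negative wind speed (arbitrary units; scene generation
#'   samples it uniformly on `[0, 1]` by default).
#' @param direction azimuth in radians, normalised to `[0, 2*pi)`
#'   (0 points along +x).
#' @return An object of class `wind_state`.
#' @export
wind_state <- function(speed, direction) {
  if (!is_scalar_num(speed) || speed < 0) stopf("wind speed must be >= 0")
  if (!is_scalar_num(direction)) stopf("wind direction must be a finite scalar")
  structure(list(speed = speed, direction = wrap_angle(direction)),
            class = "wind_state")
}

#' Wind-driven bend schedule for one stem
#'
#' Converts a wind state into per-segment pitch offsets applied while
#' interpreting the stem's expanded string. The offset of segment `k` of `n`
#' is `base_bend * speed * k / n` (bending grows toward the tip), and the bend
#' azimuth is the wind direction plus a single per-stem Gaussian jitter, so
#' stems in one scene lean coherently but not identically. Draws from the
#' current RNG stream.
#'
#' @param spec an [lsystem_spec()]; expanded internally to count segments.
#' @param wind a [wind_state()].
#' @param jitter_sd standard deviation (radians) of the per-stem azimuth
#'   jitter.
#' @return List with `offsets` (numeric, one pitch per forward segment) and
#'   `azimuth` (scalar bend azimuth in radians).
#' @export
wind_modulate <- function(spec, wind, jitter_sd = 0.15) {
  stopifnot(inherits(spec, "lsystem_spec"), inherits(wind, "wind_state"))
  n <- sum(strsplit(expand_lsystem(spec), "")[[1]] == "F")
  if (wind$speed == 0) {
    return(list(offsets = numeric(n), azimuth = wind$direction))
  }
  offsets <- spec$base_bend * wind$speed * seq_len(n) / n
  azimuth <- wrap_angle(wind$direction + stats::rnorm(1, sd = jitter_sd))
  list(offsets = offsets, azimuth = azimuth)
}

# pitch `heading` toward the horizontal direction at `azimuth` by `theta`
pitch_toward <- function(heading, azimuth, theta) {
  if (theta == 0) return(heading)
  target <- c(cos(azimuth), sin(azimuth), 0)
  axis <- pracma_cross(heading, target)
  if (sqrt(sum(axis^2)) < 1e-12) return(heading) # heading already horizontal
  rotate_about(heading, axis, theta)
}

#' Interpret an expanded string as a stem polyline
#'
#' Standard 3D turtle: the heading starts vertical (+z); each "F" first
#' applies the wind-schedule pitch for that segment, then draws one segment of
#' `step_length`; "+"/"-" pitch the heading by `+/- base_bend * bend_scale`
#' toward the schedule azimuth; "[" / "]" push / pop turtle state.
#'
#' @param symbols expanded symbol string.
#' @param bends schedule from [wind_modulate()] (or `NULL` for no wind).
#' @param base origin of the stem (length-3 numeric).
#' @param spec the [lsystem_spec()] providing `step_length` and `base_bend`.
#' @param bend_scale multiplier on `base_bend` for the "+"/"-" symbols; scene
#'   generation sets it to the wind speed so still air leaves stems straight.
#' @return An object of class `stem_geometry`: `polyline` (n x 3 matrix),
#'   `head_anchor` (last vertex), `head_axis` (unit direction of the last
#'   segment).
#' @export
interpret_stem <- function(symbols, bends = NULL, base = c(0, 0, 0),
                           spec = lsystem_spec(), bend_scale = 1) {
  syms <- strsplit(symbols, "")[[1]]
  bad <- setdiff(syms, spec$alphabet)
  if (length(bad)) stopf("unknown symbols: %s", paste(unique(bad), collapse = " "))
  n_f <- sum(syms == "F")
  if (n_f == 0L) stopf("string has no drawable content")
  offsets <- if (is.null(bends)) numeric(n_f) else bends$offsets
  azimuth <- if (is.null(bends)) 0 else bends$azimuth
  if (length(offsets) < n_f) stopf("bend schedule shorter than segment count")

  pos <- as.numeric(base)
  heading <- c(0, 0, 1)
  stack <- list()
  pts <- matrix(0, nrow = n_f + 1L, ncol = 3L)
  pts[1L, ] <- pos
  k <- 0L
  np <- 1L
  for (sym in syms) {
    if (sym == "F") {
      k <- k + 1L
      heading <- pitch_toward(heading, azimuth, offsets[k])
      pos <- pos + spec$step_length * heading
      np <- np + 1L
      pts[np, ] <- pos
    } else if (sym == "+") {
      heading <- pitch_toward(heading, azimuth, spec$base_bend * bend_scale)
    } else if (sym == "-") {
      heading <- pitch_toward(heading, azimuth, -spec$base_bend * bend_scale)
    } else if (sym == "[") {
      stack[[length(stack) + 1L]] <- list(pos = pos, heading = heading)
    } else if (sym == "]") {
      if (!length(stack)) stopf("unbalanced ']' in symbol string")
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pos <- st$pos
      heading <- st$heading
    }
  }
  polyline <- pts[seq_len(np), , drop = FALSE]
  last_seg <- polyline[np, ] - polyline[np - 1L, ]
  structure(
    list(polyline = polyline,
         head_anchor = polyline[np, ],
         head_axis = unit3(last_seg)),
    class = "stem_geometry")
}
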