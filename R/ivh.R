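#' Load an intraventricular haemorrhage scoring schema
#'
#' Schemas are data, not code: YAML files describing the ventricular
#' compartments, their fill-level thresholds and scores, the score for a
#' full-and-expanded compartment, and any per-ventricle expansion bonus.
#' Two schemas ship with the package:
#'
#' * `"classic"`: the Graeb scale - lateral ventricles scored 1 (trace of
#'   blood) to 4 (ventricle full of blood and expanded), third and fourth
#'   ventricles scored 1 (blood present) or 2 (filled with blood and
#'   expanded); maximum score 12.
#' * `"mgs32"`: the modified Graeb scale - eight ventricular compartments
#'   (frontal-horn-plus-body, temporal horn and occipital horn on each
#'   side, plus the third and fourth ventricles), each scored 1-4 by
#'   quartile of blood filling; maximum score 32. The extra point per
#'   expanded ventricle is exposed through `expansion_bonus` and is off by
#'   default so the nominal maximum of 32 holds.
#'
#' @param schema `"classic"`, `"mgs32"`, or a path to a schema YAML file.
#' @param expansion_bonus Optional override of the schema's per-ventricle
#'   expansion bonus (points per expanded blood-containing ventricle).
#' @return An object of class `graeb_schema`.
#' @export
graeb_schema <- function(schema = c("classic", "mgs32"),
                         expansion_bonus = NULL) {
  if (length(schema) > 1L || schema %in% c("classic", "mgs32")) {
    schema <- match.arg(schema)
    path <- system.file("extdata", "schemas", paste0(schema, ".yaml"),
                        package = "ichvol", mustWork = TRUE)
  } else {
    path <- schema
  }
  raw <- yaml::read_yaml(path)
  comps <- lapply(raw$compartments, function(cc) {
    fs <- do.call(rbind, lapply(cc$fill_scores, function(l) {
      data.frame(max = l$max, score = l$score)
    }))
    if (is.unsorted(fs$max, strictly = TRUE) || is.unsorted(fs$score)) {
      stop("fill thresholds must be strictly increasing with non-decreasing scores",
           call. = FALSE)
    }
    list(name = cc$name, ventricle = cc$ventricle,
         trace_score = cc$trace_score %||% 0L,
         fill_scores = fs,
         full_expanded_score = cc$full_expanded_score)
  })
  if (!is.null(expansion_bonus)) raw$expansion_bonus <- expansion_bonus
  structure(
    list(name = raw$name,
         compartments = comps,
         expansion_bonus = raw$expansion_bonus %||% 0,
         full_fill = raw$full_fill %||% 0.999),
    class = "graeb_schema"
  )
}

#' @export
print.graeb_schema <- function(x, ...) {
  cat(sprintf("<graeb_schema> %s: %d compartments, expansion bonus %g, max score %d\n",
              x$name, length(x$compartments), x$expansion_bonus, schema_max(x)))
  invisible(x)
}

#' Ventricular blood state
#'
#' Per-compartment blood fill fractions plus per-ventricle expansion
#' flags. `trace` marks blood that is present but fills a negligible
#' fraction (the classic scale distinguishes a trace from fraction-based
#' levels, so it is a flag rather than an epsilon fill).
#'
#' @param compartments A data frame with columns `compartment`,
#'   `ventricle`, `fill` (in `[0,1]`), `trace` (logical) and `expanded`
#'   (logical, constant within a ventricle).
#' @return An object of class `ventricular_state` (a tibble).
#' @export
ventricular_state <- function(compartments) {
  df <- tibble::as_tibble(compartments)
  need <- c("compartment", "ventricle", "fill", "trace", "expanded")
  if (!all(need %in% names(df))) {
    stop("state needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$fill < 0 | df$fill > 1)) {
    stop("fill fractions must lie in [0, 1]", call. = FALSE)
  }
  bad <- df$expanded & !(df$fill > 0 | df$trace)
  if (any(bad)) {
    stop("a ventricle can only be expanded if it contains blood", call. = FALSE)
  }
  class(df) <- c("ventricular_state", class(df))
  df
}

#' Preset ventricular states for a schema
#'
#' @param preset `"empty"` (no blood anywhere) or `"maximal"` (every
#'   compartment full, every expansion criterion met).
#' @param schema A [graeb_schema()].
#' @return A [ventricular_state()].
#' @export
ventricular_preset <- function(preset = c("empty", "maximal"),
                               schema = graeb_schema("mgs32")) {
  preset <- match.arg(preset)
  df <- tibble::tibble(
    compartment = vapply(schema$compartments, `[[`, "", "name"),
    ventricle = vapply(schema$compartments, `[[`, "", "ventricle"),
    fill = if (preset == "maximal") 1 else 0,
    trace = FALSE,
    expanded = preset == "maximal"
  )
  ventricular_state(df)
}

# Match state rows to one schema compartment, aggregating finer
# compartments of the same ventricle when no exact name matches.
state_rows_for <- function(state, comp) {
  rows <- state[state$compartment == comp$name, , drop = FALSE]
  if (nrow(rows) == 0L) {
    rows <- state[state$ventricle == comp$ventricle, , drop = FALSE]
  }
  rows
}

score_compartment <- function(rows, comp, full_fill) {
  fill <- mean(rows$fill)
  trace <- any(rows$trace)
  expanded <- any(rows$expanded)
  if (fill <= 0 && !trace) return(0L)
  if (!is.null(comp$full_expanded_score) && expanded && fill >= full_fill) {
    return(as.integer(comp$full_expanded_score))
  }
  if (fill <= 0 && trace) return(as.integer(comp$trace_score))
  i <- which(fill <= comp$fill_scores$max + 1e-12)[1]
  if (is.na(i)) i <- nrow(comp$fill_scores)
  as.integer(comp$fill_scores$score[i])
}

score_state <- function(state, schema) {
  stopifnot(inherits(schema, "graeb_schema"))
  state <- ventricular_state(state)
  missing <- character(0)
  total <- 0L
  for (comp in schema$compartments) {
    rows <- state_rows_for(state, comp)
    if (nrow(rows) == 0L) {
      missing <- c(missing, comp$name)
      next
    }
    total <- total + score_compartment(rows, comp, schema$full_fill)
  }
  if (length(missing) > 0L) {
    stop("state is missing compartments: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (schema$expansion_bonus > 0) {
    vent <- unique(state$ventricle)
    for (v in vent) {
      rows <- state[state$ventricle == v, ]
      if (any(rows$expanded) && (any(rows$fill > 0) || any(rows$trace))) {
        total <- total + schema$expansion_bonus
      }
    }
  }
  as.integer(total)
}

#' Classic Graeb score
#'
#' Scores the amount of intraventricular blood: each lateral ventricle
#' 1 (trace) to 4 (full of blood and expanded), the third and fourth
#' ventricles 1 (blood present) or 2 (filled with blood and expanded),
#' summed to a maximum of 12. States described at the finer modified-Graeb
#' compartment level are aggregated per ventricle (mean fill, any trace,
#' any expansion) before scoring.
#'
#' @param state A [ventricular_state()].
#' @param schema A [graeb_schema()]; defaults to the classic scale.
#' @return Integer score, 0 when no blood is present.
#' @export
graeb_score <- function(state, schema = graeb_schema("classic")) {
  score_state(state, schema)
}

#' Modified Graeb score
#'
#' Scores eight ventricular compartments by quartile of blood filling
#' (1: any up to 25%, 2: up to 50%, 3: up to 75%, 4: over 75%), summing to
#' a maximum of 32 under the default schema. A per-ventricle expansion
#' bonus can be enabled on the schema.
#'
#' @param state A [ventricular_state()].
#' @param schema A [graeb_schema()]; defaults to the 32-point scale.
#' @return Integer score, 0 when no blood is present.
#' @export
modified_graeb_score <- function(state, schema = graeb_schema("mgs32")) {
  score_state(state, schema)
}

#' Maximum attainable score of a schema
#'
#' Computed by scoring the maximal state (all compartments full, all
#' expansion criteria met), not read from a stored constant, so it also
#' validates hand-written schema files.
#'
#' @param schema A [graeb_schema()].
#' @return Integer maximum score.
#' @export
schema_max <- function(schema) {
  score_state(ventricular_preset("maximal", schema), schema)
}

#' Draw a random ventricular state
#'
#' Samples a plausible IVH pattern on a schema's compartments: with
#' probability `p_no_ivh` there is no blood at all; otherwise each
#' ventricle is involved with its own probability, involved ventricles
#' receive a severity drawn from a Beta distribution, compartment fills
#' scatter around the ventricle severity, near-zero fills become traces,
#' and nearly full ventricles may be expanded.
#'
#' @param seed Integer seed.
#' @param schema A [graeb_schema()] supplying the compartment layout.
#' @param p_no_ivh Probability of a completely blood-free state.
#' @return A [ventricular_state()].
#' @export
generate_ventricular_state <- function(seed, schema = graeb_schema("mgs32"),
                                       p_no_ivh = 0.25) {
  withr::with_seed(seed, {
    comp <- vapply(schema$compartments, `[[`, "", "name")
    vent <- vapply(schema$compartments, `[[`, "", "ventricle")
    uv <- unique(vent)
    fill <- numeric(length(comp))
    expanded <- logical(length(comp))
    if (stats::runif(1) >= p_no_ivh) {
      p_involved <- ifelse(grepl("^lateral", uv), 0.7,
                           ifelse(uv == "third", 0.5, 0.4))
      involved <- stats::runif(length(uv)) < p_involved
      sev <- stats::rbeta(length(uv), 0.8, 1.6) * involved
      for (i in seq_along(uv)) {
        idx <- vent == uv[i]
        if (!involved[i]) next
        f <- pmin(1, pmax(0, sev[i] * stats::rlnorm(sum(idx), 0, 0.3)))
        fill[idx] <- f
        expanded[idx] <- mean(f) > 0.75 && stats::runif(1) < 0.5
      }
    }
    trace <- fill > 0 & fill < 0.02
    fill[trace] <- 0
    ventricular_state(tibble::tibble(
      compartment = comp, ventricle = vent,
      fill = fill, trace = trace, expanded = expanded & (fill > 0 | trace)
    ))
  })
}
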