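#' Validate a report configuration
#'
#' Parses a YAML (or JSON) report configuration and checks it, collecting
#' every problem rather than stopping at the first. A configuration names
#' exactly one input source — a packaged `fixture`, inline `summary`
#' performance (one mapping or a list of them), or a `predictions` CSV path
#' — plus the population, sweep axis, output formats and styling options.
#' For fixture inputs, `source: counts` (the default) reports the fixture's
#' prose-derived reference cells, while `source: summaries` re-derives the
#' cells from the printed sensitivity/specificity/prevalence.
#'
#' @param x Path to a config file, or the raw config text itself.
#' @return On success, a list of class `report_config`; on failure, a
#'   character vector of messages (one per problem, naming the offending
#'   field) of class `config_errors`. Errors are returned, never thrown.
#' @examples
#' validate_config("fixture: qrisk2\nformats: [markdown]\n")
#' @export
validate_config <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  raw <- tryCatch(yaml::yaml.load(txt), error = function(e) e)
  if (inherits(raw, "error")) {
    raw <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                    error = function(e) e)
  }
  if (inherits(raw, "error") || !is.list(raw)) {
    return(structure("config: not parseable as YAML or JSON",
                     class = "config_errors"))
  }

  errs <- character()
  err <- function(msg) errs <<- c(errs, msg)

  sources <- intersect(c("fixture", "summary", "predictions"), names(raw))
  if (length(sources) == 0L) {
    err("input: exactly one of `fixture`, `summary`, `predictions` is required")
  } else if (length(sources) > 1L) {
    err(sprintf("input: multiple sources given (%s); exactly one is allowed",
                paste(sources, collapse = ", ")))
  }
  if (!is.null(raw$fixture) &&
      !(is.character(raw$fixture) && raw$fixture %in% c("csrs", "qrisk2"))) {
    err("fixture: must be \"csrs\" or \"qrisk2\"")
  }
  population <- raw$population %||% 1000
  if (!is.numeric(population) || length(population) != 1L || population < 1 ||
      abs(population - round(population)) > 1e-8) {
    err("population: must be a positive integer")
  }
  formats <- unlist(raw$formats %||% list("svg", "csv", "markdown"))
  bad <- setdiff(formats, c("svg", "csv", "markdown", "html"))
  if (length(formats) == 0L) {
    err("formats: at least one of svg, csv, markdown, html is required")
  } else if (length(bad)) {
    err(sprintf("formats: unknown format(s) %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$summary)) {
    summaries <- if (!is.null(raw$summary$sensitivity)) list(raw$summary)
                 else raw$summary
    for (i in seq_along(summaries)) {
      s <- summaries[[i]]
      for (key in c("sensitivity", "specificity", "prevalence")) {
        v <- s[[key]]
        if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
          err(sprintf("summary[%d].%s: must be a proportion in [0, 1]", i, key))
        }
      }
    }
  }
  if (!is.null(raw$predictions)) {
    if (!is.character(raw$predictions)) {
      err("predictions: must be a file path")
    } else if (!file.exists(raw$predictions)) {
      err(sprintf("predictions: file not found: %s", raw$predictions))
    }
    if (is.null(raw$cutpoints)) {
      err("cutpoints: required with a predictions input")
    }
  }
  if (!is.null(raw$prevalences) &&
      (!is.numeric(unlist(raw$prevalences)) ||
       any(unlist(raw$prevalences) <= 0 | unlist(raw$prevalences) >= 1))) {
    err("prevalences: all values must lie strictly in (0, 1)")
  }
  source <- raw$source %||% "counts"
  if (!source %in% c("counts", "summaries")) {
    err("source: must be \"counts\" or \"summaries\"")
  }
  if (!is.null(raw$grid)) {
    for (key in c("rows", "cols")) {
      v <- raw$grid[[key]]
      if (!is.null(v) && (!is.numeric(v) || v < 1)) {
        err(sprintf("grid.%s: must be a positive integer", key))
      }
    }
  }
  if (length(errs)) return(structure(errs, class = "config_errors"))

  structure(list(
    fixture = raw$fixture,
    summary = raw$summary,
    predictions = raw$predictions,
    cutpoints = unlist(raw$cutpoints),
    source = source,
    prevalences = unlist(raw$prevalences),
    population = as.integer(population),
    formats = formats,
    grid = raw$grid,
    style = raw$style,
    out_dir = raw$out_dir,
    digits = raw$digits %||% 2
  ), class = "report_config")
}

narrative_for <- function(table) {
  m <- nf_metrics(table)
  tmpl <- paste(readLines(system.file("templates", "narrative.txt",
                                      package = "natfreq"),
                          warn = FALSE), collapse = "\n")
  txt <- interpolate(tmpl, list(
    population = table$population, events = m$events,
    non_events = m$non_events, at_risk = m$at_risk,
    not_at_risk = m$not_at_risk, tp = table$tp, fp = table$fp,
    fn = table$fn, tn = table$tn))
  if (!is.na(m$overtreat_ratio) && m$overtreat_ratio > 0) {
    extra <- paste(readLines(system.file("templates",
                                         "narrative_overtreat.txt",
                                         package = "natfreq"),
                             warn = FALSE), collapse = "\n")
    txt <- paste0(txt, "\n",
                  interpolate(extra,
                              list(overtreat = round(m$overtreat_ratio))))
  }
  txt
}

slug <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "-", x)
  gsub("^-|-$", "", tolower(x))
}

#' Generate a full natural-frequency report bundle
#'
#' Runs the whole pipeline for one configuration: builds the
#' natural-frequency sweep for the configured input, renders one population
#' diagram per row, generates a per-row narrative in whole-person counts
#' (every number interpolated from the same table objects the sweep holds,
#' never recomputed ad hoc), and writes the requested formats to the output
#' directory. With a fixed configuration the artifacts are byte-identical
#' across runs.
#'
#' @param config A `report_config` from [validate_config()], or raw config
#'   text/path which will be validated first.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#'   Created if missing. When neither is given, nothing is written and the
#'   bundle is only returned.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the sweep, per-row narratives, rendered
#'   documents and the paths written.
#' @export
run_report <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "report_config")) {
    config <- validate_config(config)
    if (inherits(config, "config_errors")) {
      stop(paste(c("invalid report config:", config), collapse = "\n  "),
           call. = FALSE)
    }
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  # Resolve the input source into a sweep.
  if (!is.null(config$fixture)) {
    fx <- case_study_fixture(config$fixture)
    sweep <- if (!is.null(config$prevalences)) {
      s <- fx$summaries[[1]]
      sweep_prevalence(s$sensitivity, s$specificity, config$prevalences,
                       config$population)
    } else if (config$source == "counts" && length(fx$counts)) {
      # the fixtures' prose-derived cells are the authoritative natural
      # frequencies; rescale if a different reference population is asked for
      tables <- lapply(fx$counts, function(t) {
        if (t$population != config$population) nf_rescale(t, config$population)
        else t
      })
      sweep_from_tables(tables)
    } else {
      sweep_cutpoints(fx$summaries, config$population)
    }
  } else if (!is.null(config$summary)) {
    raws <- if (!is.null(config$summary$sensitivity)) list(config$summary)
            else config$summary
    summaries <- lapply(seq_along(raws), function(i) {
      s <- raws[[i]]
      perf_summary(s$sensitivity, s$specificity, s$prevalence,
                   s$label %||% sprintf("cut-point %d", i))
    })
    sweep <- if (!is.null(config$prevalences)) {
      s <- summaries[[1]]
      sweep_prevalence(s$sensitivity, s$specificity, config$prevalences,
                       config$population)
    } else {
      sweep_cutpoints(summaries, config$population)
    }
  } else {
    data <- read_predictions(config$predictions)
    sweep <- sweep_cutpoints_pred(data, config$cutpoints)
  }

  for (r in sweep$rows) {
    say("row %-28s tp %4d fp %4d fn %4d tn %4d", r$label, r$table$tp,
        r$table$fp, r$table$fn, r$table$tn)
    if (length(r$table$flags)) {
      say("row %s: flags: %s", r$label, paste(r$table$flags, collapse = ", "))
    }
    if (length(r$metrics$undefined)) {
      say("row %s: undefined metrics: %s", r$label,
          paste(r$metrics$undefined, collapse = ", "))
    }
  }

  grid <- grid_spec(rows = config$grid$rows %||% 40,
                    cols = config$grid$cols %||% 25)
  style <- nf_style(palette = config$style$palette %||% "default")

  diagrams <- lapply(sweep$rows, function(r) {
    render_svg(nf_layout(r$table, grid), style, caption = r$label)
  })
  names(diagrams) <- vapply(sweep$rows, `[[`, "", "label")
  narratives <- lapply(sweep$rows, function(r) narrative_for(r$table))
  names(narratives) <- names(diagrams)

  docs <- list()
  if ("csv" %in% config$formats) docs$csv <- sweep_to_table(sweep, "csv", config$digits)
  if ("markdown" %in% config$formats) {
    docs$markdown <- paste0(sweep_to_table(sweep, "markdown", config$digits),
                            "\n\n", paste(unlist(narratives), collapse = "\n\n"),
                            "\n")
  }
  if ("html" %in% config$formats) {
    docs$html <- paste0(
      "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
      "<title>natural-frequency report</title></head><body>\n<pre>\n",
      sweep_to_table(sweep, "markdown", config$digits), "\n</pre>\n",
      paste(vapply(names(diagrams), function(nm) {
        paste0("<h3>", nm, "</h3>\n<p>", narratives[[nm]], "</p>\n",
               diagrams[[nm]])
      }, ""), collapse = "\n"),
      "</body></html>\n")
  }

  out_dir <- out_dir %||% config$out_dir
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(name, text) {
      path <- file.path(out_dir, name)
      writeLines(text, path, sep = "")
      files <<- c(files, path)
      say("wrote %s", path)
    }
    if (!is.null(docs$csv)) wr("sweep.csv", docs$csv)
    if (!is.null(docs$markdown)) wr("report.md", docs$markdown)
    if (!is.null(docs$html)) wr("report.html", docs$html)
    if ("svg" %in% config$formats) {
      for (nm in names(diagrams)) {
        wr(paste0("diagram-", slug(nm), ".svg"), diagrams[[nm]])
      }
    }
  }

  invisible(list(sweep = sweep, diagrams = diagrams,
                 narratives = narratives, documents = docs, files = files))
}
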