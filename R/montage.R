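# Montage selection and derivation: referential 10-20/10-10 presets, the
# longitudinal bipolar ("double banana") chain, custom text-file montages,
# and hemisphere classification used for trace colouring.

#' Hemisphere of a 10-20 style electrode label
#'
#' Classifies by the standard 10-20 numbering convention: an odd terminal
#' number is left hemisphere, an even one right, and a `z`/`Z` suffix the
#' midline. Bipolar derivation names such as `"FP1-F7"` inherit the
#' hemisphere of their first (plus) electrode. Labels that fit none of
#' these patterns return the `"unknown"` sentinel rather than erroring, so
#' non-EEG channels (e.g. `"ECG"`) render in a neutral colour.
#'
#' @param label character vector of electrode or derivation labels.
#' @return character vector over `{"left", "right", "midline", "unknown"}`.
#' @export
#' @examples
#' hemisphere_of(c("C3", "C4", "Cz", "FP1-F7", "ECG"))
hemisphere_of <- function(label) {
  vapply(as.character(label), function(l) {
    l <- trimws(l)
    plus <- strsplit(l, "-", fixed = TRUE)[[1L]][1L]
    plus <- normalize_electrode(plus)
    if (grepl("^[A-Z]+[0-9]+$", plus)) {
      num <- as.integer(sub("^[A-Z]+", "", plus))
      if (num %% 2L == 1L) "left" else "right"
    } else if (grepl("^[A-Z]+Z$", plus) && nchar(plus) > 1L) {
      "midline"
    } else {
      "unknown"
    }
  }, character(1L), USE.NAMES = FALSE)
}

# canonical electrode token: upper case, "EEG " prefix and "-REF"/"-LE"
# reference decorations stripped
normalize_electrode <- function(label) {
  l <- toupper(trimws(label))
  l <- sub("^EEG\\s+", "", l)
  l <- sub("[-_ ](REF|LE|AVG|A1|A2)$", "", l)
  trimws(l)
}

new_montage <- function(name, derivations) {
  stopifnot(is.data.frame(derivations),
            all(c("name", "plus", "minus") %in% names(derivations)))
  if (anyDuplicated(derivations$name)) {
    stop_edfviz("duplicate derivation name: ",
                derivations$name[duplicated(derivations$name)][1L],
                class = "edfviz_parse_error")
  }
  both <- !is.na(derivations$minus)
  if (any(derivations$plus[both] == derivations$minus[both])) {
    stop_edfviz("derivation with identical plus and minus electrode",
                class = "edfviz_parse_error")
  }
  derivations$hemisphere <- hemisphere_of(derivations$plus)
  rownames(derivations) <- NULL
  structure(list(name = name, derivations = derivations),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> '", x$name, "': ", nrow(x$derivations),
      " derivation(s)\n", sep = "")
  cat(" ", paste(x$derivations$name, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in montage presets
#'
#' Returns one of the shipped presets: the 19-electrode referential 10-20
#' montage, an extended referential 10-10 montage, or the 18-derivation
#' longitudinal bipolar 10-20 ("double banana") chain
#' (FP1-F7, F7-T3, T3-T5, T5-O1, FP2-F8, ..., FZ-CZ, CZ-PZ). The presets
#' are stored as editable text files under
#' `system.file("extdata/montages", package = "edfviz")` in the
#' [parse_custom_montage()] grammar.
#'
#' @param kind one of `"ten_twenty"`, `"ten_ten"`, `"bipolar_ten_twenty"`.
#' @return An `eeg_montage`.
#' @export
#' @examples
#' builtin_montage("bipolar_ten_twenty")
builtin_montage <- function(kind = c("ten_twenty", "ten_ten",
                                     "bipolar_ten_twenty")) {
  kind <- match.arg(kind)
  path <- system.file("extdata", "montages", paste0(kind, ".txt"),
                      package = "edfviz", mustWork = TRUE)
  m <- parse_custom_montage(path)
  m$name <- kind
  m
}

#' Parse a custom montage definition file
#'
#' One derivation per line. A bare electrode label (`"C3"`) defines a
#' referential derivation; `"NAME = PLUS - MINUS"` defines a bipolar
#' difference. Whitespace is tolerated, blank lines and `#` comments are
#' skipped. Hemispheres are inferred with [hemisphere_of()].
#'
#' @param path path to the text file.
#' @return An `eeg_montage` named after the file.
#' @section Errors: duplicate derivation names and malformed lines raise a
#'   parse error reporting the line number.
#' @export
parse_custom_montage <- function(path) {
  if (!file.exists(path)) {
    stop_edfviz("montage file not found: ", path, class = "edfviz_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  name <- character(0); plus <- character(0); minus <- character(0)
  for (i in seq_along(lines)) {
    l <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(l)) next
    if (grepl("=", l, fixed = TRUE)) {
      m <- regmatches(l, regexec("^([^=]+)=\\s*(\\S+)\\s*-\\s*(\\S+)\\s*$", l))[[1L]]
      if (length(m) != 4L) {
        stop_edfviz("malformed montage line ", i, ": '", lines[i], "'",
                    class = "edfviz_parse_error")
      }
      dn <- trimws(m[2L]); dp <- trimws(m[3L]); dm <- trimws(m[4L])
    } else {
      if (!grepl("^\\S+$", l)) {
        stop_edfviz("malformed montage line ", i, ": '", lines[i], "'",
                    class = "edfviz_parse_error")
      }
      dn <- l; dp <- l; dm <- NA_character_
    }
    if (dn %in% name) {
      stop_edfviz("duplicate derivation '", dn, "' at line ", i,
                  class = "edfviz_parse_error")
    }
    name <- c(name, dn); plus <- c(plus, dp); minus <- c(minus, dm)
  }
  if (!length(name)) {
    stop_edfviz("montage file defines no derivations: ", path,
                class = "edfviz_parse_error")
  }
  new_montage(basename(path),
              data.frame(name = name, plus = plus, minus = minus,
                         stringsAsFactors = FALSE))
}

resolve_electrode <- function(electrode, recording) {
  want <- normalize_electrode(electrode)
  norm <- normalize_electrode(names(recording$channels))
  hit <- which(norm == want)
  if (length(hit) == 0L) {
    stop_edfviz("electrode '", electrode, "' matches no channel; available: ",
                paste(names(recording$channels), collapse = ", "),
                class = "edfviz_lookup_error")
  }
  if (length(hit) > 1L) {
    stop_edfviz("electrode '", electrode, "' is ambiguous; candidates: ",
                paste(names(recording$channels)[hit], collapse = ", "),
                class = "edfviz_lookup_error")
  }
  hit
}

#' Apply a montage to a recording
#'
#' Resolves every electrode named by the montage to exactly one recording
#' channel (case-insensitively, after stripping `"EEG "` prefixes and
#' `"-REF"`/`"-LE"` style reference decorations, so montage entry `"C3"`
#' matches a channel labelled `"EEG C3-REF"`) and derives the display
#' channels: referential derivations pass the channel through unchanged,
#' bipolar derivations are `samples(plus) - samples(minus)` and require
#' equal sample rates. Output order is montage order.
#'
#' @param recording an [eeg_recording()].
#' @param montage an `eeg_montage`.
#' @return An object of class `derived_channels`: a list with `names`,
#'   `hemispheres`, `sample_rates` and `samples` (list of numeric vectors),
#'   in montage order.
#' @section Errors: unresolvable or ambiguous electrodes raise a lookup
#'   error listing the candidates; mixed sample rates inside one bipolar
#'   derivation raise a rate error.
#' @export
apply_montage <- function(recording, montage) {
  validate_recording(recording)
  stopifnot(inherits(montage, "eeg_montage"))
  d <- montage$derivations
  samples <- vector("list", nrow(d))
  rates <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    jp <- resolve_electrode(d$plus[i], recording)
    if (is.na(d$minus[i])) {
      samples[[i]] <- recording$channels[[jp]]
      rates[i] <- recording$sample_rates[jp]
    } else {
      jm <- resolve_electrode(d$minus[i], recording)
      if (recording$sample_rates[jp] != recording$sample_rates[jm]) {
        stop_edfviz("derivation '", d$name[i], "' mixes sample rates ",
                    recording$sample_rates[jp], " and ",
                    recording$sample_rates[jm], " Hz",
                    class = "edfviz_rate_error")
      }
      samples[[i]] <- recording$channels[[jp]] - recording$channels[[jm]]
      rates[i] <- recording$sample_rates[jp]
    }
  }
  structure(
    list(names = d$name, hemispheres = d$hemisphere,
         sample_rates = rates, samples = samples),
    class = "derived_channels"
  )
}

#' @export
print.derived_channels <- function(x, ...) {
  cat("<derived_channels> ", length(x$names), " trace(s) at ",
      paste(unique(x$sample_rates), collapse = ", "), " Hz\n", sep = "")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}
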