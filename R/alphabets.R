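# SSE alphabets and reductions. Every other module is parameterized by an
# alphabet object; '-' is the universal gap character and never a member of
# any alphabet.

.alphabet_registry <- new.env(parent = emptyenv())

#' Define an SSE alphabet
#'
#' An SSE alphabet is a named, ordered set of single-character secondary
#' structure codes. Two alphabets ship with the package: `"q3"`, the
#' three-state set \{H, E, C\} (helix, strand, coil), and `"dssp8"`, the
#' DSSP eight-state set \{G, H, I, E, B, T, S, C\} (3-10 helix, alpha helix,
#' pi helix, extended strand, beta bridge, turn, bend, coil). User-defined
#' alphabets may be registered with [register_sse_alphabet()].
#'
#' @param name Short identifier of a registered alphabet.
#' @return An object of class `sse_alphabet`: a list with elements `name`,
#'   `codes` (character vector of single characters) and `description`.
#' @examples
#' sse_alphabet("q3")$codes
#' sse_alphabet("dssp8")$codes
#' @export
sse_alphabet <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stop("`name` must be a single string", call. = FALSE)
  obj <- get0(name, envir = .alphabet_registry, inherits = FALSE)
  if (is.null(obj))
    stop("unknown SSE alphabet: '", name, "' (registered: ",
         paste(ls(.alphabet_registry), collapse = ", "), ")", call. = FALSE)
  obj
}

#' Register an SSE alphabet
#'
#' @param name Short identifier (e.g. `"q3"`).
#' @param codes Character vector of unique single-character codes; the gap
#'   character `-` is not allowed.
#' @param description Free-text description.
#' @return The registered `sse_alphabet`, invisibly.
#' @export
register_sse_alphabet <- function(name, codes, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  codes <- as.character(codes)
  if (any(nchar(codes) != 1L))
    stop("alphabet codes must be single characters", call. = FALSE)
  if (anyDuplicated(codes))
    stop("alphabet codes must be unique", call. = FALSE)
  if ("-" %in% codes)
    stop("the gap character '-' cannot be an alphabet code", call. = FALSE)
  obj <- structure(
    list(name = name, codes = codes, description = description),
    class = "sse_alphabet")
  assign(name, obj, envir = .alphabet_registry)
  invisible(obj)
}

#' @export
print.sse_alphabet <- function(x, ...) {
  cat("SSE alphabet '", x$name, "': {", paste(x$codes, collapse = ", "),
      "}\n", sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Define a reduction between two SSE alphabets
#'
#' A reduction is a total map from every source code to a target code. The
#' shipped `dssp8 -> q3` reduction follows the standard convention: helices
#' \{H, G, I\} -> H, strands \{E, B\} -> E, coils \{C, S, T\} -> C.
#'
#' @param source,target `sse_alphabet` objects or registered names.
#' @param mapping Named character vector, `names(mapping)` the source codes
#'   and values the target codes. Omit to use the built-in mapping when
#'   source and target are `dssp8`/`q3`, or the identity when
#'   `source$name == target$name`.
#' @return An object of class `sse_reduction`.
#' @examples
#' r <- sse_reduction("dssp8", "q3")
#' reduce_sse("GHIEBTSC", r)
#' @export
sse_reduction <- function(source, target, mapping = NULL) {
  if (is.character(source)) source <- sse_alphabet(source)
  if (is.character(target)) target <- sse_alphabet(target)
  if (is.null(mapping)) {
    if (identical(source$name, target$name)) {
      mapping <- stats::setNames(source$codes, source$codes)
    } else if (source$name == "dssp8" && target$name == "q3") {
      mapping <- c(G = "H", H = "H", I = "H",
                   E = "E", B = "E",
                   T = "C", S = "C", C = "C")
    } else {
      stop("no built-in mapping from '", source$name, "' to '",
           target$name, "'; supply `mapping`", call. = FALSE)
    }
  }
  if (!setequal(names(mapping), source$codes))
    stop("mapping must cover every source code exactly once", call. = FALSE)
  if (!all(mapping %in% target$codes))
    stop("mapping values must be target codes", call. = FALSE)
  if (!all(target$codes %in% mapping))
    stop("every target code must be the image of >=1 source code",
         call. = FALSE)
  structure(list(source = source, target = target,
                 mapping = mapping[source$codes]),
            class = "sse_reduction")
}

#' Reduce SSE strings from one alphabet to another
#'
#' Applies a reduction character-by-character. The gap character `-` passes
#' through unchanged. Reduction with `source == target` is the identity.
#'
#' @param s Character vector of SSE strings over the source alphabet.
#' @param reduction An [sse_reduction()]; default reduces `dssp8` to `q3`.
#' @return Character vector of the same lengths over the target alphabet.
#' @examples
#' reduce_sse("GHIEBTSC")  # "HHHEECCC"
#' @export
reduce_sse <- function(s, reduction = sse_reduction("dssp8", "q3")) {
  stopifnot(inherits(reduction, "sse_reduction"))
  map <- c(reduction$mapping, "-" = "-")
  vapply(s, function(one) {
    if (!nzchar(one)) return(one)
    chars <- strsplit(one, "")[[1]]
    out <- map[chars]
    if (anyNA(out)) {
      bad <- which(is.na(out))[1]
      stop("invalid code '", chars[bad], "' at position ", bad,
           " for alphabet '", reduction$source$name, "'", call. = FALSE)
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate an SSE string over an alphabet; errors name the first offending
# position. Gaps optionally allowed. Returns the (upper-cased) string.
validate_sse_string <- function(s, alphabet, allow_gap = FALSE, id = NULL) {
  if (s != toupper(s)) {
    warning("SSE string", if (!is.null(id)) paste0(" '", id, "'"),
            " upper-cased on read", call. = FALSE)
    s <- toupper(s)
  }
  chars <- strsplit(s, "")[[1]]
  ok <- chars %in% alphabet$codes
  if (allow_gap) ok <- ok | chars == "-"
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("invalid code '", chars[bad], "' at position ", bad,
         if (!is.null(id)) paste0(" in record '", id, "'"),
         " for alphabet '", alphabet$name, "'", call. = FALSE)
  }
  s
}

#' Load alphabet definitions from a flat key-value config file
#'
#' The config is a plain-text file of `key = value` lines. Recognized keys:
#' `name`, `codes` (codes concatenated, e.g. `HEC`), `description`, and
#' optionally `reduce_to` plus `mapping` (pairs like `G:H,H:H,...`). Blank
#' lines and lines starting with `#` are ignored. The alphabet is
#' registered and returned; when `reduce_to`/`mapping` are present the
#' reduction is returned in the `reduction` attribute.
#'
#' @param path Path to the config file.
#' @return The registered `sse_alphabet`, invisibly.
#' @export
read_alphabet_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: '", lines[which(bad)[1]], "'", call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  for (req in c("name", "codes"))
    if (!req %in% names(vals))
      stop("alphabet config missing key '", req, "'", call. = FALSE)
  alpha <- register_sse_alphabet(vals[["name"]],
                                 strsplit(vals[["codes"]], "")[[1]],
                                 if ("description" %in% names(vals))
                                   vals[["description"]] else "")
  if ("reduce_to" %in% names(vals)) {
    if (!"mapping" %in% names(vals))
      stop("config has 'reduce_to' but no 'mapping'", call. = FALSE)
    pairs <- strsplit(strsplit(vals[["mapping"]], ",")[[1]], ":")
    map <- stats::setNames(vapply(pairs, `[`, character(1), 2L),
                           vapply(pairs, `[`, character(1), 1L))
    attr(alpha, "reduction") <-
      sse_reduction(alpha, sse_alphabet(vals[["reduce_to"]]), map)
  }
  invisible(alpha)
}

# The 20-residue amino-acid alphabet is registered so the same profile
# machinery produces the classic AA-PSSM. 'X' (unknown) is deliberately not
# a member: unknown residues contribute no occurrence mass.
.onLoad <- function(libname, pkgname) {
  register_sse_alphabet("q3", c("H", "E", "C"),
    "three-state secondary structure: helix, strand, coil")
  register_sse_alphabet("dssp8", c("G", "H", "I", "E", "B", "T", "S", "C"),
    "DSSP eight-state secondary structure")
  register_sse_alphabet("aa20", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    "20 standard amino acids (for the classic AA-PSSM)")
}
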