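# Mouse-to-human gene-symbol mapping through a primary ortholog table with
# a manual-override fallback.

# Mouse convention: capitalized; human convention: uppercase.
norm_mouse <- function(x) {
  x <- tolower(trimws(x))
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}
norm_human <- function(x) toupper(trimws(x))

#' Read an ortholog table
#'
#' TSV with columns `mouse_symbol`, `human_symbol`, `source` (`primary` or
#' `manual`). Symbols are case-normalized (mouse capitalized, human
#' uppercase); malformed rows are rejected with their line numbers.
#'
#' @param path Ortholog TSV path.
#' @return An `ortholog_table` data.frame.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("mouse_symbol", "human_symbol", "source")
  if (!all(need %in% names(df))) {
    stop("ortholog table ", path, " must have columns ",
         paste(need, collapse = ","))
  }
  bad <- which(!nzchar(trimws(df$mouse_symbol)) |
                 !nzchar(trimws(df$human_symbol)) |
                 !df$source %in% c("primary", "manual"))
  if (length(bad)) {
    stop("malformed ortholog rows at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  ortholog_table(df$mouse_symbol, df$human_symbol, df$source)
}

#' Construct an ortholog table in memory
#'
#' @param mouse_symbol,human_symbol Character vectors of symbols.
#' @param source `"primary"` or `"manual"` per row.
#' @return An `ortholog_table` data.frame with normalized symbols.
#' @export
ortholog_table <- function(mouse_symbol, human_symbol,
                           source = "primary") {
  df <- data.frame(mouse_symbol = norm_mouse(mouse_symbol),
                   human_symbol = norm_human(human_symbol),
                   source = source, stringsAsFactors = FALSE)
  stopifnot(all(df$source %in% c("primary", "manual")),
            all(nzchar(df$mouse_symbol)), all(nzchar(df$human_symbol)))
  dup <- duplicated(df[, c("mouse_symbol", "human_symbol", "source")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Map mouse symbols to human orthologs
#'
#' Each symbol resolves through the primary source first, falling back to the
#' manual source; one-to-many mappings are expanded with a flag. Unresolved
#' symbols are returned in input order.
#'
#' @param mouse_symbols Character vector of mouse symbols (any case).
#' @param table An `ortholog_table`.
#' @return List with `mapped` (data.frame mouse_symbol, human_symbol, source,
#'   one_to_many) and `unmapped` (character vector in input order).
#' @export
map_symbols <- function(mouse_symbols, table) {
  stopifnot(inherits(table, "ortholog_table"))
  qs <- norm_mouse(mouse_symbols)
  rows <- vector("list", length(qs))
  unmapped <- character(0)
  for (i in seq_along(qs)) {
    hit <- table[table$mouse_symbol == qs[i] & table$source == "primary", ]
    if (!nrow(hit)) {
      hit <- table[table$mouse_symbol == qs[i] & table$source == "manual", ]
    }
    if (!nrow(hit)) {
      unmapped <- c(unmapped, mouse_symbols[i])
    } else {
      rows[[i]] <- data.frame(mouse_symbol = qs[i],
                              human_symbol = hit$human_symbol,
                              source = hit$source,
                              one_to_many = nrow(hit) > 1,
                              stringsAsFactors = FALSE)
    }
  }
  mapped <- do.call(rbind, rows)
  if (is.null(mapped)) {
    mapped <- data.frame(mouse_symbol = character(0),
                         human_symbol = character(0),
                         source = character(0), one_to_many = logical(0),
                         stringsAsFactors = FALSE)
  }
  rownames(mapped) <- NULL
  list(mapped = mapped, unmapped = unmapped)
}
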