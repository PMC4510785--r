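#' Read an intervention cost ledger from CSV
#'
#' Reads an itemized micro-costing table (one priced resource line per row)
#' and builds a [cost_ledger()]. The CSV mirrors the published build-up of the
#' intervention's delivery cost: columns `category` (one of `delivery`,
#' `extra_consultations`, `extra_treatments`), `label`, `centre` (`Cambridge`,
#' `Leicester` or `shared`), `unit_rate` (GBP per hour or per item),
#' `quantity` (hours or items), `multiplicity` (persons or sessions) and
#' `lump_sum` (an override in GBP for rows costed by internal accounting or
#' already discounted). Exactly one of {`unit_rate` x `quantity` x
#' `multiplicity`, `lump_sum`} must be available per row.
#'
#' @param path Path to the CSV file. Defaults to the packaged table of
#'   intervention delivery costs (2009/10 GBP).
#' @param ... Passed on to [cost_ledger()].
#' @return A `cost_ledger` object.
#' @export
read_cost_items <- function(path = system.file("extdata", "intervention_costs.csv",
                                               package = "diabcea"), ...) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("category", "label", "centre", "unit_rate", "quantity",
              "multiplicity", "lump_sum")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols) > 0L) {
    stop("cost item file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  cost_ledger(items, ...)
}

#' Resolve one cost item to pounds
#'
#' A row's value is `unit_rate * quantity * multiplicity` unless a
#' `lump_sum` override is present, in which case the override governs the row
#' (used for internally accounted rows and pre-discounted consultation rows).
#'
#' @param item A one-row data frame (or list) with fields `unit_rate`,
#'   `quantity`, `multiplicity`, `lump_sum`.
#' @return Resolved value in GBP (unrounded).
#' @examples
#' resolve_item(list(unit_rate = 44, quantity = 8, multiplicity = 2,
#'                   lump_sum = NA))  # 704
#' @export
resolve_item <- function(item) {
  lump <- item$lump_sum
  if (length(lump) == 1L && !is.na(lump)) {
    computed <- c(item$unit_rate, item$quantity, item$multiplicity)
    if (any(!is.na(computed))) {
      stop("cost item '", item$label,
           "': exactly one of computed amount or lump_sum may govern the row")
    }
    return(as.numeric(lump))
  }
  parts <- c(unit_rate = item$unit_rate, quantity = item$quantity,
             multiplicity = item$multiplicity)
  if (any(is.na(parts))) {
    stop("cost item '", item$label, "': missing ",
         paste(names(parts)[is.na(parts)], collapse = ", "),
         " and no lump_sum override")
  }
  if (any(parts < 0)) stop("cost item '", item$label, "': negative components")
  as.numeric(item$unit_rate) * as.numeric(item$quantity) *
    as.numeric(item$multiplicity)
}

#' Present value of a multi-year cost stream
#'
#' Year 1 is undiscounted; year t is weighted by `(1 + rate)^-(t - 1)`,
#' following the convention that costs and QALYs incurred after the first
#' year are discounted (default 3.5% per annum).
#'
#' @param amounts Numeric vector, amount per year (year 1 first).
#' @param rate Annual discount rate as a proportion (>= 0).
#' @return Discounted sum in the units of `amounts`.
#' @examples
#' discounted_stream(c(100, 100, 100), 0.035)  # 289.97
#' @export
discounted_stream <- function(amounts, rate = 0.035) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("discount rate must be a single non-negative number")
  }
  if (length(amounts) == 0L) return(0)
  sum(amounts * discount_weights(length(amounts), rate))
}

# discount weights (1+r)^-(t-1) for t = 1..n
discount_weights <- function(n, rate) (1 + rate)^-(seq_len(n) - 1L)

#' Build a cost ledger
#'
#' A ledger holds resolved cost rows plus the reporting conventions: the
#' discount rate, a single price-year inflation multiplier (to the 2009/10 UK
#' level) and the per-person denominator (the intensive-arm headcount).
#'
#' @param items Data frame of cost items (see [read_cost_items()]).
#' @param discount_rate Annual discount rate (informational; pre-discounted
#'   rows enter as lump sums).
#' @param price_year_factor Multiplier applied to every resolved row to move
#'   it to the reporting price year (default 1, i.e. already at 2009/10).
#' @param n_per_person Denominator for per-person costs (default 513, the
#'   intensive-treatment arm).
#' @param centre_headcount Named integer vector used to allocate `shared`
#'   rows between centres pro rata (default `c(Cambridge = 452, Leicester = 61)`).
#' @return An object of class `cost_ledger`.
#' @export
cost_ledger <- function(items, discount_rate = 0.035, price_year_factor = 1,
                        n_per_person = 513,
                        centre_headcount = c(Cambridge = 452, Leicester = 61)) {
  stopifnot(is.data.frame(items))
  if (price_year_factor < 0) stop("price_year_factor must be >= 0")
  if (nrow(items) > 0L) {
    bad <- setdiff(unique(items$category),
                   c("delivery", "extra_consultations", "extra_treatments"))
    if (length(bad) > 0L) {
      stop("unknown cost categories: ", paste(bad, collapse = ", "))
    }
    items$value <- vapply(seq_len(nrow(items)),
                          function(i) resolve_item(items[i, , drop = FALSE]),
                          numeric(1)) * price_year_factor
  } else {
    items$value <- numeric(0)
  }
  structure(list(items = items, discount_rate = discount_rate,
                 price_year_factor = price_year_factor,
                 n_per_person = n_per_person,
                 centre_headcount = centre_headcount),
            class = "cost_ledger")
}

#' Ledger totals, per-person and per-centre costs
#'
#' Aggregates resolved rows into category subtotals, the grand total, the
#' per-person cost (total over the per-person denominator) and per-centre
#' totals. Centre-tagged rows are attributed directly; `shared` rows are
#' allocated to centres pro rata to the intensive-arm centre headcount.
#' All values are returned unrounded; monetary rounding to the nearest pound
#' is applied only when printing (see `print.cost_ledger_totals`).
#'
#' @param ledger A `cost_ledger`.
#' @return A list of class `cost_ledger_totals` with elements `subtotals`
#'   (named by category), `total`, `per_person`, `per_person_components`
#'   (per-person cost by category) and `per_centre` (data frame with centre,
#'   total, headcount, per_person).
#' @export
ledger_totals <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  items <- ledger$items
  if (ledger$n_per_person == 0) stop("per-person denominator is zero")
  cats <- c("delivery", "extra_consultations", "extra_treatments")
  subtotals <- vapply(cats, function(ca) sum(items$value[items$category == ca]),
                      numeric(1))
  total <- sum(subtotals)
  hc <- ledger$centre_headcount
  shared <- sum(items$value[items$centre == "shared"])
  centre_tot <- vapply(names(hc), function(ce) {
    sum(items$value[items$centre == ce]) + shared * hc[[ce]] / sum(hc)
  }, numeric(1))
  per_centre <- data.frame(centre = names(hc), total = unname(centre_tot),
                           headcount = unname(hc),
                           per_person = unname(centre_tot / hc))
  structure(list(subtotals = subtotals, total = total,
                 per_person = total / ledger$n_per_person,
                 per_person_components = subtotals / ledger$n_per_person,
                 per_centre = per_centre),
            class = "cost_ledger_totals")
}

#' @export
print.cost_ledger_totals <- function(x, ...) {
  cat("Intervention cost totals (GBP, rounded to nearest pound)\n")
  st <- round(x$subtotals)
  for (nm in names(st)) cat(sprintf("  %-20s %10s\n", nm, format(st[[nm]], big.mark = ",")))
  cat(sprintf("  %-20s %10s\n", "total", format(round(x$total), big.mark = ",")))
  cat(sprintf("  per person: %s  (components: %s)\n",
              round(x$per_person),
              paste(round(x$per_person_components), collapse = " + ")))
  pc <- x$per_centre
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %s: total %s, per person %s (n = %d)\n", pc$centre[i],
                format(round(pc$total[i]), big.mark = ","),
                round(pc$per_person[i]), pc$headcount[i]))
  }
  invisible(x)
}

#' Write ledger totals as a tidy CSV report
#'
#' @param totals A `cost_ledger_totals` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_report <- function(totals, path) {
  stopifnot(inherits(totals, "cost_ledger_totals"))
  rows <- data.frame(
    quantity = c(paste0("subtotal_", names(totals$subtotals)), "total",
                 "per_person",
                 paste0("per_person_", names(totals$per_person_components)),
                 paste0("total_", totals$per_centre$centre),
                 paste0("per_person_", totals$per_centre$centre)),
    gbp = round(c(totals$subtotals, totals$total, totals$per_person,
                  totals$per_person_components, totals$per_centre$total,
                  totals$per_centre$per_person)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
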