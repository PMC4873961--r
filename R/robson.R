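# Robson ten-group classification (TGCS) and the group-wise CS-rate table.
#
# The ten groups partition all deliveries by parity, previous CS, plurality,
# presentation/lie, gestational age and onset of labour. The decision cascade
# below applies the groups in the standard precedence order that makes them
# mutually exclusive: multiple pregnancy (8), transverse/oblique lie (9),
# breech by parity (6/7), single cephalic preterm (10), previous uterine scar
# at term (5), then parity x onset (1-4). A record whose field is missing at
# the decision node actually reached is unclassifiable (NA).

#' Classify deliveries into the ten Robson groups
#'
#' @details
#' Operational choices: "multiparous" means parity >= 1; "previous uterine
#' scar" means previous_cs >= 1 (scars from non-caesarean uterine surgery are
#' not captured by the record schema); term means >= 37 completed weeks, so a
#' pregnancy at 36 weeks + 6 days counts as 36 weeks and falls in group 10;
#' presentation "other" is grouped with transverse/oblique lie (group 9),
#' matching the coding rule of the scoring models; "provider-initiated"
#' childbirth covers induced labour and prelabour caesarean section.
#'
#' @param x A `facility_dataset` or a data.frame of records.
#' @return Integer vector in 1..10, NA where unclassifiable.
#' @export
robson_classify <- function(x) {
  r <- if (inherits(x, "facility_dataset")) x$records else
    facility_dataset(x)$records
  n <- nrow(r)
  g <- rep(NA_integer_, n)
  done <- rep(FALSE, n)

  multiple <- r$multiple_pregnancy
  # node 1: plurality; required for everyone
  done[is.na(multiple)] <- TRUE                      # unclassifiable
  idx <- !done & multiple
  g[idx] <- 8L; done[idx] <- TRUE

  # node 2: presentation/lie (singletons only from here on)
  pres <- r$presentation
  done[!done & is.na(pres)] <- TRUE
  idx <- !done & pres %in% c("transverse_oblique", "other")
  g[idx] <- 9L; done[idx] <- TRUE

  parity <- r$parity
  idx <- !done & pres == "breech"
  done[idx & is.na(parity)] <- TRUE
  g[idx & !is.na(parity) & parity == 0L] <- 6L
  g[idx & !is.na(parity) & parity >= 1L] <- 7L
  done[idx] <- TRUE

  # cephalic singletons: gestational age
  ga <- r$gestational_age
  done[!done & is.na(ga)] <- TRUE
  idx <- !done & ga <= 36L
  g[idx] <- 10L; done[idx] <- TRUE

  # term cephalic singletons: uterine scar
  pcs <- r$previous_cs
  done[!done & is.na(pcs)] <- TRUE
  idx <- !done & pcs >= 1L
  g[idx] <- 5L; done[idx] <- TRUE

  # unscarred term cephalic singletons: parity x onset
  onset <- r$onset_of_labour
  done[!done & (is.na(parity) | is.na(onset))] <- TRUE
  idx <- !done
  nulli <- idx & parity == 0L
  spont <- onset == "spontaneous"
  g[nulli & spont] <- 1L
  g[nulli & !spont] <- 2L
  g[idx & !nulli & spont] <- 3L
  g[idx & !nulli & !spont] <- 4L
  g
}

#' Group-wise caesarean section rate table
#'
#' Classifies every record with a recorded mode of delivery and tabulates, per
#' Robson group: CS count, group size, CS rate (%), relative group size (%)
#' and the group's contribution to the overall CS rate (CS in group / all
#' classified births, %). Records without a recorded mode are excluded and
#' counted separately, as are unclassifiable records. Rates are stored at
#' full precision; the print method rounds to one decimal.
#'
#' @param ds A `facility_dataset`.
#' @return A `robson_table`: list with `table` (data.frame of 10 group rows),
#'   `overall` (one-row data.frame), `unclassifiable_count`,
#'   `missing_mode_count`.
#' @export
robson_report <- function(ds) {
  stopifnot(inherits(ds, "facility_dataset"))
  r <- ds$records
  has_mode <- !is.na(r$mode_of_delivery)
  missing_mode <- sum(!has_mode)
  sub <- r[has_mode, , drop = FALSE]
  g <- robson_classify(sub)
  classified <- !is.na(g)
  if (!any(classified)) {
    stop("no classifiable records with a recorded mode of delivery")
  }
  cs <- sub$mode_of_delivery == "caesarean"
  n_total <- sum(classified)
  group_size <- tabulate(g[classified], nbins = 10L)
  cs_count <- tabulate(g[classified & cs], nbins = 10L)
  tab <- data.frame(
    group         = 1:10,
    cs_count      = cs_count,
    group_size    = group_size,
    cs_rate       = ifelse(group_size > 0, 100 * cs_count / group_size, NA_real_),
    relative_size = 100 * group_size / n_total,
    contribution  = 100 * cs_count / n_total
  )
  overall <- data.frame(
    cs_count      = sum(cs_count),
    group_size    = n_total,
    cs_rate       = 100 * sum(cs_count) / n_total,
    relative_size = 100,
    contribution  = 100 * sum(cs_count) / n_total
  )
  structure(list(table = tab, overall = overall,
                 unclassifiable_count = sum(!classified),
                 missing_mode_count = missing_mode),
            class = "robson_table")
}

#' @export
print.robson_table <- function(x, ...) {
  tab <- x$table
  cat("Robson ten-group classification\n")
  cat(sprintf("%-6s %12s %8s %14s %14s\n", "Group", "CS/group",
              "CS rate", "Relative size", "CS/all births"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-6d %5d/%-6d %7.1f%% %13.1f%% %13.1f%%\n",
                tab$group[i], tab$cs_count[i], tab$group_size[i],
                tab$cs_rate[i], tab$relative_size[i], tab$contribution[i]))
  }
  o <- x$overall
  cat(sprintf("%-6s %5d/%-6d %7.1f%% %13.1f%% %13.1f%%\n", "All",
              o$cs_count, o$group_size, o$cs_rate, o$relative_size,
              o$contribution))
  if (x$unclassifiable_count > 0 || x$missing_mode_count > 0) {
    cat(sprintf("unclassifiable: %d; missing mode of delivery: %d\n",
                x$unclassifiable_count, x$missing_mode_count))
  }
  invisible(x)
}
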