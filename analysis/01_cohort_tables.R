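#!/usr/bin/env Rscript
# Cohort analysis from the shipped per-patient transcriptions: eligibility
# accounting, recomputation of the published summary rows, the threshold
# nesting check, and the paired t-test on SUVmax across chemoradiotherapy.
# Writes results/cohort_summary.csv and results/exclusion_log.csv.

suppressMessages(library(petbtv))
dir.create("results", showWarnings = FALSE)

## eligibility --------------------------------------------------------------
fc <- filter_cohort(read_cohort_flags())
cat(sprintf("Cohort: %d patients scanned; %d analysable pairs, %d excluded\n",
            nrow(fc$included) + nrow(fc$excluded), nrow(fc$included),
            nrow(fc$excluded)))
print(fc$reason_counts)
write.csv(fc$excluded[, c("patient", "reason")],
          "results/exclusion_log.csv", row.names = FALSE)

## published summaries, recomputed ------------------------------------------
rep <- reproduce_tables()
stopifnot(all(rep$pass))
cat(sprintf("\nAll %d printed summary values reproduced to 1 decimal:\n",
            nrow(rep)))
print(rep, row.names = FALSE)
gr <- attr(rep, "gtv_range")
cat(sprintf("\nGTV range %.1f-%.1f cm^3; Post90 fully inside Pre40 in %d/%d patients\n",
            gr[1], gr[2], attr(rep, "n_full_post90_in_pre40"),
            attr(rep, "n_analysis")))
write.csv(rep, "results/cohort_summary.csv", row.names = FALSE)

## nesting check -------------------------------------------------------------
tab1 <- read_table1()
ok <- table1_nesting_ok(tab1, read_table2()$patient)
cat(sprintf("Threshold nesting (Post90<=Post80<=Post70<=Post60, Pre50<=Pre40): %d/%d rows\n",
            sum(ok), length(ok)))

## treatment response --------------------------------------------------------
analysis <- read_table2()$patient
rows <- tab1[match(analysis, tab1$patient), ]
tt <- paired_t_test(rows$pre_suvmax, rows$post_suvmax)
cat(sprintf("\nSUVmax decrease over CRT (analysis set, n=%d): t=%.2f, df=%d, p=%.4g\n",
            nrow(rows), tt$t, tt$df, tt$p))
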