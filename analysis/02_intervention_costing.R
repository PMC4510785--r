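#!/usr/bin/env Rscript
# Stage 2: micro-cost the intervention from the packaged itemized table.
#
# Resolves every priced resource line (staff time x unit rates, materials,
# per-patient items; pre-discounted consultation rows enter as lump sums),
# aggregates category subtotals, the 5-year total, per-person components and
# per-centre totals (shared rows allocated pro rata to intensive-arm
# headcount), and writes the report under results/.

library(diabcea)

dir.create("results", showWarnings = FALSE)
ledger <- read_cost_items()
totals <- ledger_totals(ledger)
print(totals)
write_cost_report(totals, "results/intervention_costs.csv")
cat("written: results/intervention_costs.csv\n")
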