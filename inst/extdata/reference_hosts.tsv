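host	category
ncbi.nlm.nih.gov	government_official_db
pubmed.ncbi.nlm.nih.gov	government_official_db
pmc.ncbi.nlm.nih.gov	government_official_db
nih.gov	government_official_db
medlineplus.gov	government_official_db
clinicaltrials.gov	government_official_db
fda.gov	government_official_db
cdc.gov	government_official_db
genome.gov	government_official_db
ema.europa.eu	government_official_db
who.int	government_official_db
rarediseases.info.nih.gov	rare_disease_db
orpha.net	rare_disease_db
rarediseases.org	rare_disease_db
omim.org	rare_disease_db
malacards.org	rare_disease_db
hpo.jax.org	rare_disease_db
mayoclinic.org	clinical_reference
clevelandclinic.org	clinical_reference
uptodate.com	clinical_reference
merckmanuals.com	clinical_reference
msdmanuals.com	clinical_reference
medscape.com	clinical_reference
hopkinsmedicine.org	clinical_reference
wikipedia.org	encyclopedia
britannica.com	encyclopedia
sciencedirect.com	academic_journal_portal
springer.com	academic_journal_portal
link.springer.com	academic_journal_portal
nature.com	academic_journal_portal
onlinelibrary.wiley.com	academic_journal_portal
academic.oup.com	academic_journal_portal
frontiersin.org	academic_journal_portal
cell.com	academic_journal_portal
thelancet.com	academic_journal_portal
nejm.org	academic_journal_portal
bmj.com	academic_journal_portal
journals.plos.org	academic_journal_portal
mdpi.com	academic_journal_portal
karger.com	academic_journal_portal
tandfonline.com	academic_journal_portal
jamanetwork.com	academic_journal_portal
atsjournals.org	academic_journal_portal
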