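# 44-gene DBI co-expression network, compartment/category annotation.
# 34 member symbols are as printed in the source results (22 mitochondrial,
# 12 further metabolism genes); the remaining 10 members were not printed and
# are SYNTHETIC placeholders (UNNAMED_01..UNNAMED_10, compartment other,
# category unknown). Read with read.delim(..., comment.char = "#").
gene_id	compartment	category
ACAT2	mitochondrion	metabolism
ATP5MC1	mitochondrion	metabolism
ATP5MC3	mitochondrion	metabolism
ATP5MF	mitochondrion	metabolism
ATP5PF	mitochondrion	metabolism
COA3	mitochondrion	metabolism
COX13	mitochondrion	metabolism
COX5A	mitochondrion	metabolism
COX7B	mitochondrion	metabolism
HSD17B10	mitochondrion	metabolism
JTB	mitochondrion	other
MMAB	mitochondrion	metabolism
MPC2	mitochondrion	metabolism
MRPL33	mitochondrion	other
MRPL47	mitochondrion	other
NDUFA6	mitochondrion	metabolism
NDUFAB1	mitochondrion	metabolism
NDUFB2	mitochondrion	metabolism
NDUFB3	mitochondrion	metabolism
RAB5IF	mitochondrion	other
TIMM8B	mitochondrion	other
UQCRQ	mitochondrion	metabolism
ADI1	other	metabolism
COP1	other	metabolism
DHCR7	other	metabolism
EBP	other	metabolism
FDPS	other	metabolism
GCHFR	other	metabolism
H2AZ1	other	metabolism
IDH1	other	metabolism
NSDHL	other	metabolism
SNRPE	other	metabolism
SNRPG	other	metabolism
UBE2F	other	metabolism
UNNAMED_01	other	unknown
UNNAMED_02	other	unknown
UNNAMED_03	other	unknown
UNNAMED_04	other	unknown
UNNAMED_05	other	unknown
UNNAMED_06	other	unknown
UNNAMED_07	other	unknown
UNNAMED_08	other	unknown
UNNAMED_09	other	unknown
UNNAMED_10	other	unknown
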