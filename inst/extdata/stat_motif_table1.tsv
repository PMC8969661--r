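gene	region	sequence	intron1
CLDN4	upstream	TTCAGGAA	FALSE
CLDN4	upstream	TTCCAGAA	FALSE
CLDN4	upstream	TTCCCAGAA	FALSE
CLDN4	upstream	TTCCTTAGAA	FALSE
CLDN4	downstream	TTCTGGAA	FALSE
CLDN7	upstream	TTCATGAA	FALSE
CLDN7	upstream	TTCAAGAA	FALSE
CLDN7	introns1_2	TTCACCGAA	FALSE
CLDN7	introns1_2	TTCGAGGGAA	TRUE
CLDN7	downstream	TTCTGGAA	FALSE
CLDN12	upstream	TTCTGGGAA	FALSE
CLDN12	upstream	TTCACAGAA	FALSE
CLDN12	upstream	TTCAGAGGAA	FALSE
CLDN12	upstream	TTCAAGAA	FALSE
CLDN12	upstream	TTCTAGAA	FALSE
CLDN12	upstream	TTCCCTGAA	FALSE
CLDN12	upstream	TTCAGGAA	FALSE
CLDN12	upstream	TTCAATGAA	FALSE
CLDN12	upstream	TTCTTTGAA	FALSE
CLDN12	introns1_2	TTCTAAGAA	FALSE
CLDN12	introns1_2	TTCAGAGAA	FALSE
CLDN12	introns1_2	TTCTTAAGAA	FALSE
CLDN12	introns1_2	TTCTAAAGAA	FALSE
CLDN12	downstream	TTCCAGAA	FALSE
CLDN12	downstream	TTCAAGGAA	FALSE
CLDN12	downstream	TTCTATAGAA	FALSE
CLDN15	upstream	TTCCTGAA	FALSE
CLDN15	upstream	TTCTAGGAA	FALSE
CLDN15	upstream	TTCGTTGAA	FALSE
CLDN15	upstream	TTCGGGGAA	FALSE
CLDN15	downstream	TTCCAGAA	FALSE
CLDN15	downstream	TTCCCAGAA	FALSE
CLDN15	downstream	TTCAGGAA	FALSE
CLDN15	downstream	TTCTAGAA	FALSE
TJP1	upstream	TTCGAGGAA	FALSE
TJP1	upstream	TTCCCGGGAA	FALSE
TJP1	introns1_2	TTCCTGAA	TRUE
TJP1	introns1_2	TTCTTGGAA	FALSE
TJP1	introns1_2	TTCCTACGAA	TRUE
TJP1	introns1_2	TTCAGGAA	FALSE
TJP1	introns1_2	TTCTAAGAA	FALSE
TJP1	introns1_2	TTCAGCCGAA	TRUE
TJP1	introns1_2	TTCCTGAA	FALSE
TJP1	introns1_2	TTCTTGGAA	FALSE
TJP1	introns1_2	TTCTCCTGAA	FALSE
TJP1	introns1_2	TTCATGAA	FALSE
TJP1	introns1_2	TTCAGAGAA	FALSE
TJP1	introns1_2	TTCGGGAGAA	FALSE
TJP1	introns1_2	TTCTTGAA	FALSE
TJP1	introns1_2	TTCCAAGAA	FALSE
TJP1	introns1_2	TTCAGAGGAA	FALSE
TJP1	introns1_2	TTCATTGAA	FALSE
TJP1	introns1_2	TTCATTGGAA	FALSE
TJP1	introns1_2	TTCACTGAA	FALSE
TJP1	introns1_2	TTCATTGGAA	FALSE
TJP1	introns1_2	TTCCTTGAA	FALSE
TJP1	downstream	TTCTGAGAA	FALSE
TJP1	downstream	TTCCAAGGAA	FALSE
TJP1	downstream	TTCCTTGGAA	FALSE
TJP2	upstream	TTCATGAATTCCTGAA	FALSE
TJP2	upstream	TTCCACGAA	FALSE
TJP2	upstream	TTCTTGAGAATTCCATTGAA	FALSE
TJP2	introns1_2	TTCTTGAA	TRUE
TJP2	introns1_2	TTCCCTGAA	TRUE
TJP2	introns1_2	TTCCAGAGAA	TRUE
TJP2	introns1_2	TTCATGAA	TRUE
TJP2	introns1_2	TTCTTAGAA	TRUE
TJP2	introns1_2	TTCGTAGGAA	TRUE
TJP2	introns1_2	TTCAAGAA	TRUE
TJP2	introns1_2	TTCCATGAA	TRUE
TJP2	introns1_2	TTCTTGAGAA	TRUE
TJP2	introns1_2	TTCCAGAA	TRUE
TJP2	introns1_2	TTCCATGAA	TRUE
TJP2	introns1_2	TTCTTTAGAA	TRUE
TJP2	introns1_2	TTCTGGAA	TRUE
TJP2	introns1_2	TTCGTTGAA	TRUE
TJP2	introns1_2	TTCCCAGGAA	TRUE
TJP2	introns1_2	TTCCCGAA	FALSE
TJP2	introns1_2	TTCTTTGAA	TRUE
TJP2	introns1_2	TTCAGTGGAA	TRUE
TJP2	introns1_2	TTCCTGAA	FALSE
TJP2	introns1_2	TTCTCAGAA	TRUE
TJP2	introns1_2	TTCATGGGAA	TRUE
TJP2	introns1_2	TTCTCAGAA	TRUE
TJP2	introns1_2	TTCAAAGGAA	TRUE
TJP2	introns1_2	TTCAGGGAA	TRUE
TJP2	introns1_2	TTCTATGGAA	TRUE
TJP2	introns1_2	TTCATAGAA	TRUE
TJP2	introns1_2	TTCACCTGAA	TRUE
TJP2	introns1_2	TTCATTGAA	TRUE
TJP2	introns1_2	TTCCTTGGAA	FALSE
TJP2	introns1_2	TTCTATGAA	FALSE
TJP2	downstream	TTCTTGAATTCTTGAATTCCAGAA	FALSE
TJP2	downstream	TTCTCAGAATTCCTAGAATTCTGGGAA	FALSE
TJP2	downstream	TTCCTCAGAA	FALSE
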