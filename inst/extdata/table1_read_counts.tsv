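sample_id	total_reads	hq_bases	printed_trimmed_pct	unique_reads	printed_dup_pct	mapped_reads	printed_mapped_pct	read_length
GIST193_FF	63523138	5.84e9	8.1	58598506	7.8	57879604	98.8	100
GIST193_FFPE	54852570	4.97e9	9.4	49208829	10.3	48499561	98.6	100
GIST193_PB	42361296	3.80e9	10.3	39964111	5.7	39385105	98.6	100
GIST165_FF	53644770	4.95e9	7.7	49587098	7.6	49019552	98.9	100
GIST165_FFPE	50570884	4.59e9	9.3	45332397	10.4	44682820	98.6	100
GIST165_PB	42235292	3.87e9	8.3	39957754	5.4	39460107	98.8	100
GIST174_FF	56267604	5.10e9	9.3	52033110	7.5	51338819	98.7	100
GIST174_FFPE	64625134	5.87e9	9.2	58169850	10.0	57529198	98.9	100
GIST174_PB	52136904	4.69e9	10.0	48822001	6.4	48110730	98.5	100
GIST127_FF	48223180	4.42e9	8.4	44804080	7.1	44294468	98.9	100
GIST127_FFPE	14203932	1.14e9	20.7	12496962	12.0	12310812	98.1	100
GIST127_PB	43078472	3.86e9	10.4	40476585	6.0	39924959	98.4	100
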