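core_histones	replication-dependent core histone families and common variants (HGNC current and legacy symbols)	H2AC1	H2AC4	H2AC6	H2AC11	H2AC12	H2AC13	H2AC14	H2AC15	H2AC16	H2AC17	H2AC20	H2AC21	H2AZ1	H2AZ2	H2AX	MACROH2A1	H2BC1	H2BC3	H2BC4	H2BC5	H2BC6	H2BC7	H2BC8	H2BC9	H2BC10	H2BC11	H2BC12	H2BC13	H2BC14	H2BC15	H2BC17	H2BC18	H2BC21	H3C1	H3C2	H3C3	H3C4	H3C6	H3C7	H3C8	H3C10	H3C11	H3C12	H3-3A	H3-3B	H3-4	H4C1	H4C2	H4C3	H4C4	H4C5	H4C6	H4C8	H4C9	H4C11	H4C12	H4C13	H4C14	H4C15	HIST1H2AB	HIST1H2AC	HIST1H2AD	HIST1H2AE	HIST1H2AG	HIST1H2AJ	HIST1H2BB	HIST1H2BC	HIST1H2BD	HIST1H2BE	HIST1H2BK	HIST1H3A	HIST1H3B	HIST1H3D	HIST1H4A	HIST1H4B	HIST1H4C	HIST2H2AA3	HIST2H2BE	HIST2H3A	HIST2H4A	H2AFX	H2AFZ	H3F3A	H3F3B
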