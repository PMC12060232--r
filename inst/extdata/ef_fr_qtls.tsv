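qtl_id	panel	trait	lod	coeff	h2	p_qtl	p_epistasis	arm	ci_start	ci_end	overlap_group
Q1	EF	A4Back_25C	3.274	0.012	0.033	0.0591	0.736	3R	21614478	22512754
Q2	EF	Mesopl_15C	5.819	0.012	0.112	0.0006	0.699	3R	16750589	16945416
Q3	EF	Mesopl_25C	5.89	0.014	0.076	0.0003	0.714	3R	17549430	17666763
Q4	EF	Stripe_25C	6.335	0.035	0.285	0.0002	0.643	X	1057169	2420139	stripe
Q5	EF	Stripe_15C	9.924	0.071	0.176	0	0.244	X	0	2141596	stripe
Q6	EF	Wing	9.581	0.026	0.109	0	0.322	2L	12902781	13046286
Q7	EF	Wing	8.628	0.024	0.098	0	0.672	2L	22740849	23011543
Q8	EF	Wing	3.867	0.022	0.087	0.0183	0.444	3L	10353468	11407946
Q9	EF	Wing	3.526	0.019	0.059	0.0369	0.941	3R	18722896	19232530
Q10	EF	Wing	4.286	0.016	0.053	0.0073	0.183	X	20419847	20893609
Q11	FR	EtOH	3.565	22.516	0.051	0.0368	0.208	3L	10829907	11166414
Q12	FR	EtOH	3.253	27.506	0.127	0.0693	0.853	3R	3268049	3791969
Q13	FR	EtOH	3.74	19.166	0.038	0.0246	0.476	3R	23770233	24580087
Q14	FR	Song	9.111	0.019	0.079	0	0.273	3R	21997113	22171358
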