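domain_id	residue	base	contact_class	fragment_length
DBD-1	QB197	gA6	protein-backbone	10
DBD-1	QB197	aB20	protein-backbone	10
DBD-1	RB198	gA6	protein-backbone	10
DBD-1	RB198	aB20	protein-backbone	10
DBD-1	IB211	gA6	protein-backbone	10
DBD-1	IB211	aB20	protein-backbone	10
DBD-1	RA100	gA6	protein-side-chain	10
DBD-1	RA100	gA12	protein-side-chain	10
DBD-1	RA100	tA13	protein-side-chain	10
DBD-1	RA100	cB19	protein-side-chain	10
DBD-1	RA100	aB20	protein-side-chain	10
DBD-1	RA100	tB21	protein-side-chain	10
DBD-1	RA100	gB22	protein-side-chain	10
DBD-1	QB27	gA6	protein-side-chain	10
DBD-1	QB27	gA12	protein-side-chain	10
DBD-1	QB27	tA13	protein-side-chain	10
DBD-1	QB27	cB19	protein-side-chain	10
DBD-1	QB27	aB20	protein-side-chain	10
DBD-1	QB27	tB21	protein-side-chain	10
DBD-1	QB27	gB22	protein-side-chain	10
DBD-1	RB113	gA6	protein-side-chain	10
DBD-1	RB113	gA12	protein-side-chain	10
DBD-1	RB113	tA13	protein-side-chain	10
DBD-1	RB113	cB19	protein-side-chain	10
DBD-1	RB113	aB20	protein-side-chain	10
DBD-1	RB113	tB21	protein-side-chain	10
DBD-1	RB113	gB22	protein-side-chain	10
DBD-1	QB197	gA6	protein-side-chain	10
DBD-1	QB197	gA12	protein-side-chain	10
DBD-1	QB197	tA13	protein-side-chain	10
DBD-1	QB197	cB19	protein-side-chain	10
DBD-1	QB197	aB20	protein-side-chain	10
DBD-1	QB197	tB21	protein-side-chain	10
DBD-1	QB197	gB22	protein-side-chain	10
DBD-1	EB201	gA6	protein-side-chain	10
DBD-1	EB201	gA12	protein-side-chain	10
DBD-1	EB201	tA13	protein-side-chain	10
DBD-1	EB201	cB19	protein-side-chain	10
DBD-1	EB201	aB20	protein-side-chain	10
DBD-1	EB201	tB21	protein-side-chain	10
DBD-1	EB201	gB22	protein-side-chain	10
DBD-1	IB211	gA6	protein-side-chain	10
DBD-1	IB211	gA12	protein-side-chain	10
DBD-1	IB211	tA13	protein-side-chain	10
DBD-1	IB211	cB19	protein-side-chain	10
DBD-1	IB211	aB20	protein-side-chain	10
DBD-1	IB211	tB21	protein-side-chain	10
DBD-1	IB211	gB22	protein-side-chain	10
DBD-1	QB212	gA6	protein-side-chain	10
DBD-1	QB212	gA12	protein-side-chain	10
DBD-1	QB212	tA13	protein-side-chain	10
DBD-1	QB212	cB19	protein-side-chain	10
DBD-1	QB212	aB20	protein-side-chain	10
DBD-1	QB212	tB21	protein-side-chain	10
DBD-1	QB212	gB22	protein-side-chain	10
DBD-1	EB215	gA6	protein-side-chain	10
DBD-1	EB215	gA12	protein-side-chain	10
DBD-1	EB215	tA13	protein-side-chain	10
DBD-1	EB215	cB19	protein-side-chain	10
DBD-1	EB215	aB20	protein-side-chain	10
DBD-1	EB215	tB21	protein-side-chain	10
DBD-1	EB215	gB22	protein-side-chain	10
DBD-2	PA10	tB29	protein-backbone	10
DBD-2	PA10	cB30	protein-backbone	10
DBD-2	AA20	tB29	protein-backbone	10
DBD-2	AA20	cB30	protein-backbone	10
DBD-2	PA10	gA8	protein-side-chain	10
DBD-2	PA10	aA9	protein-side-chain	10
DBD-2	PA10	gB27	protein-side-chain	10
DBD-2	PA10	aB28	protein-side-chain	10
DBD-2	PA10	tB29	protein-side-chain	10
DBD-2	PA10	cB30	protein-side-chain	10
DBD-2	AA16	gA8	protein-side-chain	10
DBD-2	AA16	aA9	protein-side-chain	10
DBD-2	AA16	gB27	protein-side-chain	10
DBD-2	AA16	aB28	protein-side-chain	10
DBD-2	AA16	tB29	protein-side-chain	10
DBD-2	AA16	cB30	protein-side-chain	10
DBD-2	AA20	gA8	protein-side-chain	10
DBD-2	AA20	aA9	protein-side-chain	10
DBD-2	AA20	gB27	protein-side-chain	10
DBD-2	AA20	aB28	protein-side-chain	10
DBD-2	AA20	tB29	protein-side-chain	10
DBD-2	AA20	cB30	protein-side-chain	10
DBD-2	KA22	gA8	protein-side-chain	10
DBD-2	KA22	aA9	protein-side-chain	10
DBD-2	KA22	gB27	protein-side-chain	10
DBD-2	KA22	aB28	protein-side-chain	10
DBD-2	KA22	tB29	protein-side-chain	10
DBD-2	KA22	cB30	protein-side-chain	10
DBD-2	TA26	gA8	protein-side-chain	10
DBD-2	TA26	aA9	protein-side-chain	10
DBD-2	TA26	gB27	protein-side-chain	10
DBD-2	TA26	aB28	protein-side-chain	10
DBD-2	TA26	tB29	protein-side-chain	10
DBD-2	TA26	cB30	protein-side-chain	10
DBD-2	QA197	gA8	protein-side-chain	10
DBD-2	QA197	aA9	protein-side-chain	10
DBD-2	QA197	gB27	protein-side-chain	10
DBD-2	QA197	aB28	protein-side-chain	10
DBD-2	QA197	tB29	protein-side-chain	10
DBD-2	QA197	cB30	protein-side-chain	10
DBD-2	IA200	gA8	protein-side-chain	10
DBD-2	IA200	aA9	protein-side-chain	10
DBD-2	IA200	gB27	protein-side-chain	10
DBD-2	IA200	aB28	protein-side-chain	10
DBD-2	IA200	tB29	protein-side-chain	10
DBD-2	IA200	cB30	protein-side-chain	10
DBD-3	KA116	cA18	protein-side-chain	10
DBD-3	KA116	aA19	protein-side-chain	10
DBD-3	KA116	tA20	protein-side-chain	10
DBD-3	KA116	gA21	protein-side-chain	10
DBD-3	KA116	tB38	protein-side-chain	10
DBD-3	RA117	cA18	protein-side-chain	10
DBD-3	RA117	aA19	protein-side-chain	10
DBD-3	RA117	tA20	protein-side-chain	10
DBD-3	RA117	gA21	protein-side-chain	10
DBD-3	RA117	tB38	protein-side-chain	10
DBD-3	EA120	cA18	protein-side-chain	10
DBD-3	EA120	aA19	protein-side-chain	10
DBD-3	EA120	tA20	protein-side-chain	10
DBD-3	EA120	gA21	protein-side-chain	10
DBD-3	EA120	tB38	protein-side-chain	10
DBD-3	EA125	cA18	protein-side-chain	10
DBD-3	EA125	aA19	protein-side-chain	10
DBD-3	EA125	tA20	protein-side-chain	10
DBD-3	EA125	gA21	protein-side-chain	10
DBD-3	EA125	tB38	protein-side-chain	10
DBD-3	RA198	cA18	protein-side-chain	10
DBD-3	RA198	aA19	protein-side-chain	10
DBD-3	RA198	tA20	protein-side-chain	10
DBD-3	RA198	gA21	protein-side-chain	10
DBD-3	RA198	tB38	protein-side-chain	10
DBD-3	EA202	cA18	protein-side-chain	10
DBD-3	EA202	aA19	protein-side-chain	10
DBD-3	EA202	tA20	protein-side-chain	10
DBD-3	EA202	gA21	protein-side-chain	10
DBD-3	EA202	tB38	protein-side-chain	10
DBD-3	KA204	cA18	protein-side-chain	10
DBD-3	KA204	aA19	protein-side-chain	10
DBD-3	KA204	tA20	protein-side-chain	10
DBD-3	KA204	gA21	protein-side-chain	10
DBD-3	KA204	tB38	protein-side-chain	10
DBD-3	LA208	cA18	protein-side-chain	10
DBD-3	LA208	aA19	protein-side-chain	10
DBD-3	LA208	tA20	protein-side-chain	10
DBD-3	LA208	gA21	protein-side-chain	10
DBD-3	LA208	tB38	protein-side-chain	10
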