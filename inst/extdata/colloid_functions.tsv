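# Catalogue of sum-of-products Boolean functions mined from colloid substrates.
# One row per (function id, source table) occurrence; phi is the experimental
# discovery frequency (metadata only, never used in computation; empty = not
# reported). uncertain=1 flags entries whose printed source is typographically
# ambiguous and was transcribed conservatively.
# Transcription audit: f21 has 41 product terms (asserted by the loader).
id	arity	expression	phi	substrate	table	uncertain
f1	2	!A + !B	73	ZnO	1a	0
f2	2	A + B	45	ZnO	1a	0
f3	2	!A + B	37	ZnO	1a	0
f4	2	A + !B	33	ZnO	1a	0
f5	2	A * B	8	ZnO	1a	0
f6	2	B * !A	6	ZnO	1a	0
f7	2	(A * !B) + (B * !A)	4	ZnO	1a	0
f8	2	(A * B) + (!A * !B)	3	ZnO	1a	0
f9	2	A * !B	3	ZnO	1a	0
f10	2	!A * !B	2	ZnO	1a	0
f11	4	(A * !B) + (B * !A * !C) + (B * !C * !D)	7	ZnO	1b	0
f12	4	(C * D * !B) + (A * !B * !D) + (B * !A * !D) + (D * !A * !C)	6	ZnO	1b	0
f13	4	(A * !B * !D) + (B * !A * !C * !D)	6	ZnO	1b	0
f14	4	(!A * !D) + (A * B * C * D) + (B * !A * !C) + (C * !A * !B)	5	ZnO	1b	0
f15	4	(A * !B * !D) + (B * !A * !C) + (B * !C * !D)	5	ZnO	1b	0
f16	4	A * D * !B * !C	5	ZnO	1b	0
f17	4	A * !B * !C * !D	5	ZnO	1b	0
f18	4	(B * C * D) + (B * C * !A) + (C * D * !A) + (A * !B * !C * !D)	5	ZnO	1b	0
f19	4	(A * D * !B) + (B * D * !A) + (A * !B * !C) + (B * !A * !C) + (D * !A * !C)	5	ZnO	1b	0
f20	4	(D * !A) + (D * !B) + (B * !A * !C)	5	ZnO	1b	0
f21	8	(A * B * F * !C * !E) + (A * D * F * !C * !E) + (A * G * H * !B * !C) + (B * D * E * !A * !F) + (B * E * H * !A * !C) + (C * D * E * !B * !F) + (D * E * H * !B * !G) + (D * F * H * !A * !B) + (B * C * D * F * G * !H) + (B * C * D * G * H * !F) + (B * E * !A * !G * !H) + (C * F * !B * !G * !H) + (E * H * !A * !C * !F) + (F * H * !B * !D * !E) + (A * C * E * G * !B * !D) + (A * E * F * G * !C * !D) + (B * D * E * G * !C * !F) + (B * E * F * G * !A * !D) + (C * F * G * H * !D * !E) + (A * C * D * E * F * H * !G) + (B * !C * !E * !G * !H) + (C * !B * !D * !F * !G) + (D * !C * !E * !F * !H) + (E * !A * !B * !D * !H) + (E * !B * !D * !G * !H) + (B * C * D * !A * !E * !G) + (B * D * F * !C * !G * !H) + (B * D * G * !A * !C * !E) + (B * E * H * !C * !F * !G) + (C * D * G * !B * !E * !H) + (C * E * F * !D * !G * !H) + (C * G * H * !A * !E * !F) + (D * E * F * !A * !B * !C) + (B * D * !E * !F * !G * !H) + (B * F * !A * !D * !E * !G) + (C * D * !A * !B * !E * !H) + (C * H * !D * !E * !F * !G) + (A * C * E * G * !D * !F * !H) + (A * !B * !C * !F * !G * !H) + (D * !A * !B * !C * !E * !G) + (G * !A * !C * !D * !E * !H)		ZnO	1c	0
f22	2	A + B	35	ZnO	1d	0
f23	2	A * B	3	ZnO	1d	0
f24	4	A + B + C + D	16	ZnO	1e	0
f25	4	(A * B * D * !C) + (C * D * !A * !B)	6	ZnO	1e	0
f26	4	(C * D) + (A * B * D)	4	ZnO	1e	0
f27	4	A + B + D	2	ZnO	1e	0
f28	8	!A + !B + !C + !D + !E + !F + !G	4	ZnO	1f	0
f29	8	A * C * D * E * F * G * H * !B	2	ZnO	1f	0
f30	8	A + C + D + E + F + H + (B * !G) + (G * !B)	1	ZnO	1f	0
f31	8	C + D + E + F + H + (A * B) + (A * !G) + (B * !G) + (G * !A * !B)	1	ZnO	1f	0
const0	2	0	19	proteinoid	2a	0
f22	2	A + B	16	proteinoid	2a	0
f23	2	A * B	3	proteinoid	2a	0
f24	4	A + B + C + D	23	proteinoid	2b	0
f32	4	A * B * C * D	4	proteinoid	2b	0
f33	4	A + B + (C * D)	3	proteinoid	2b	0
f34	4	(A * B) + (B * D) + (C * D) + (A * !C * !D)	3	proteinoid	2b	0
f35	8	!A + !B + !C + !D + !E + !F + !G + !H	19	proteinoid	2c	0
f36	8	(A * !E) + (B * !H) + (C * !G) + (D * !F) + (E * !D) + (F * !C) + (G * !B) + (H * !A)	4	proteinoid	2c	0
f37	8	A * B * C * D * E * F * H * !G	2	proteinoid	2c	0
f38	8	(C * !B) + (C * !D) + (D * !E) + (E * !G) + (F * !H) + (G * !F) + (H * !E) + (A * B * !C) + (A * H * !B) + (B * H * !C)	1	proteinoid	2c	1
f23	2	A * B	21	mixture	2d	0
f22	2	A + B	14	mixture	2d	0
f39	4	!A + !B + !C	15	mixture	2e	0
f40	4	(A * !B) + (B * !C) + (D * !A)	7	mixture	2e	0
f41	4	A * B * D * !C	5	mixture	2e	0
f42	4	(A * B * !C) + (A * D * !B) + (B * D * !C)	4	mixture	2e	0
f43	8	A + B + C + D + E + F + G + H	6	mixture	2f	0
f44	8	A * B * C * D * E * F * G * !H	3	mixture	2f	0
f45	8	(A * !D) + (B * !G) + (C * !F) + (D * !E) + (E * !C) + (F * !B) + (G * !A) + (G * !H)	2	mixture	2f	0
f46	8	A + C + D + E + (B * F) + (B * G) + (B * H) + (F * G) + (F * H) + (G * H)	1	mixture	2f	1
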