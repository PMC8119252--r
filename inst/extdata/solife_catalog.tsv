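item_id	short_label	subscale	reverse_keyed
1	Alcohol food	IN	FALSE
2	Difficulty starting	CD	FALSE
3	Dancing dull	IA	FALSE
4	New foods	IA	FALSE
5	Enjoy few	IA	FALSE
6	Urge harmful shocking	IN	FALSE
7	Almost hears thoughts	UE	FALSE
8	Average mood	IN	FALSE
9	Mindreading	UE	FALSE
10	Difficulty conversation	CD	FALSE
11	Thinking before doing	IN	FALSE
12	Magical powers	UE	FALSE
13	Too independent	IA	FALSE
14	Ideas fast	UE	FALSE
15	Aware by thinking	UE	FALSE
16	Thought so real	UE	FALSE
17	Mood up and down	CD	FALSE
18	Difficulty keep interested	CD	FALSE
19	Dread going into a room	CD	FALSE
20	Accidents mysterious	UE	FALSE
21	Mixing with people	IA	FALSE
22	Difficulty controlling thoughts	CD	FALSE
23	Friends touch	IA	FALSE
24	Urge break smash	IN	FALSE
25	Urge injure yourself	IN	FALSE
26	Distracted daydreams	CD	FALSE
27	Distracted too much happens	CD	FALSE
28	Vague danger	UE	FALSE
29	Massage	IA	FALSE
30	Average person	IN	FALSE
31	Other afraid of you	IN	FALSE
32	Mirror face unusual	UE	FALSE
33	Shapes in the dark	UE	FALSE
34	Evil presence	UE	FALSE
35	Hard to make decisions	CD	FALSE
36	City lights	IA	FALSE
37	Strong smell	UE	FALSE
38	Words mixed up	CD	FALSE
39	Do the opposite	IN	FALSE
40	Close to friends	IA	FALSE
41	Spend money	IN	FALSE
42	Distracted read or talk	CD	FALSE
43	Watch TV or go out	IA	FALSE
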