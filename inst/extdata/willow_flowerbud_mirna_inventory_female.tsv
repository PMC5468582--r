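name	seq	LM	arm	location	LP
ssu-miR162a	UCGAUAAACCUCUGCAUCCAG	21	3p	seq459792:217..303:+	86
ssu-miR162b	UCGAUAAACCUCUGCAUCCAG	21	3p	seq351845:128..215:-	87
ssu-miR162c	UCGAUAAACCUCUGCAUCCAG	21	3p	seq365695:26..113:+	87
ssu-miR166	GGAAUGUUGUCUGGCUCGAGG	21	5p	seq576601:133..255:+	122
ssu-miR169	CAGCCAAGGAUGACUUGCCGG	21	3p	seq292249:428..483:-,seq292249:488..543:-	55
ssu-miR390	CGCUAUCCAUCCUGAGUUUCA	21	3p	seq242088:345..447:-	102
ssu-miR172a	AGAAUCCUGAUGAUGCUGCAG	21	5p	seq288542:116..254:+,seq263722:286..424:+,seq600570:208..346:-	138
ssu-miR472a	UUUUCCCAACUCCACCCAUCCC	22	3p	seq62383:374..435:-	61
ssu-miR472b	UUUUCCCAACUCCACCCAUCCC	22	3p	seq355906:377..445:-	68
ssu-miR1448	CUUUCCAACGCCUCCCAUAC	20	3p	seq140125:105..174:+	69
ssu-miR6423	CCGCUGUCGCCACUAUCUUCCU	22	5p	seq431318:268..328:+,seq593886:92..152:+	60
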