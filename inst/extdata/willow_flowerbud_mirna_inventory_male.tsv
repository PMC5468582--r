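name	seq	LM	arm	location	LP
ssu-miR156a	UGACAGAAGAUAGAGAGCAC	20	5p	seq517259:84..165:+	81
ssu-miR156b	UGACAGAAGAUAGAGAGCAC	20	5p	seq325710:29..80:-	51
ssu-miR160	UGCCUGGCUCCCUGUAUGCC	20	5p	seq145824:369..444:-	75
ssu-miR167a	AGAUCAUGUGGCAGUUUCACC	21	3p	seq137705:68..140:+,seq383115:96..168:+	72
ssu-miR167b	AGAUCAUGUGGCAGUUUCACC	21	3p	seq450474:97..169:+	72
ssu-miR167c	AGAUCAUGUGGCAGUUUCACC	21	3p	seq460555:421..495:-,seq460555:481..555:-	74
ssu-miR162a	UCGAUAAACCUCUGCAUCCAG	21	3p	seq430376:217..303:+	86
ssu-miR162d	UGGAGGCAGCGGUUCAUCGAUC	22	5p	seq344645:410..500:+	90
ssu-miR169a	CAGCCAAGGAUGACUUGCCGG	21	5p	seq159785:89..210:-	121
ssu-miR169b	CAGCCAAGGAUGACUUGCCGG	21	5p	seq167083:107..214:+,seq166207:31..138:+	107
ssu-miR172b	GCAGCACCAUCAAGAUUCACA	21	5p	seq555414:28..136:+	108
ssu-miR172c	GCAGCACCAUCAAGAUUCACA	21	5p	seq562308:14..122:-	108
ssu-miR396a	UUCCACAGCUUUCUUGAACUG	21	3p	seq114772:89..196:+	107
ssu-miR396b	UUCCACAGCUUUCUUGAACUG	21	3p	seq307347:218..305:-	87
ssu-miR472a	UUUUCCCAACUCCACCCAUCCC	22	3p	seq467610:63..125:+	62
ssu-miR472c	UCUUGCCUACUCCUCCCAUUCC	22	3p	seq106361:38..109:+	71
ssu-miR1448a	CUUUCCAACGCCUCCCAUAC	20	3p	seq106361:219..287:+	68
ssu-miR1448b	CUUUCCAACGCCUCCCAUAC	20	3p	seq83628:392..461:-,seq83628:422..491:-	69
ssu-miR7841	GGGGGUUGCUGUCAAGCAUAA	21	3p	seq306990:54..154:-	100
ssu-miR6423a	CCGCUGUCGCCACUAUCUUCCU	22	5p	seq268392:35..125:+	90
ssu-miR6423b	CCGCUGUCGCCACUAUCUUCCU	22	5p	seq228745:13..103:+	90
ssu-miR6423c	CCGCUGUCGCCACUAUCUUCCU	22	5p	seq199601:0..96:+	96
ssu-miR6423d	CCGCUGUCGCCACUAUCUUCCU	22	5p	seq100248:45..105:-,seq148917:45..105:-	60
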