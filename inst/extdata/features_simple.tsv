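symbol	vowel	voice	nasal	high	low	back	round	long	stress	hightone
p	-	-	-	-	-	-	-	-	-	-
b	-	+	-	-	-	-	-	-	-	-
t	-	-	-	-	-	-	-	-	-	-
d	-	+	-	-	-	-	-	-	-	-
k	-	-	-	-	-	-	-	-	-	-
g	-	+	-	-	-	-	-	-	-	-
m	-	+	+	-	-	-	-	-	-	-
n	-	+	+	-	-	-	-	-	-	-
ŋ	-	+	+	-	-	-	-	-	-	-
f	-	-	-	-	-	-	-	-	-	-
v	-	+	-	-	-	-	-	-	-	-
s	-	-	-	-	-	-	-	-	-	-
z	-	+	-	-	-	-	-	-	-	-
ʃ	-	-	-	+	-	-	-	-	-	-
ʒ	-	+	-	+	-	-	-	-	-	-
h	-	-	-	-	-	-	-	-	-	-
l	-	+	-	-	-	-	-	-	-	-
r	-	+	-	-	-	-	-	-	-	-
w	-	+	-	+	-	+	+	-	-	-
y	-	+	-	+	-	-	-	-	-	-
i	+	+	-	+	-	-	-	-	-	-
e	+	+	-	-	-	-	-	+	-	-
ε	+	+	-	-	-	-	-	-	-	-
æ	+	+	-	-	+	-	-	-	-	-
a	+	+	-	-	+	+	-	-	-	-
ә	+	+	-	-	-	+	-	-	-	-
o	+	+	-	-	-	+	+	+	-	-
ɔ	+	+	-	-	-	+	+	-	-	-
u	+	+	-	+	-	+	+	-	-	-
í	+	+	-	+	-	-	-	-	-	+
é	+	+	-	-	-	-	-	+	-	+
á	+	+	-	-	+	+	-	-	-	+
ó	+	+	-	-	-	+	+	+	-	+
ú	+	+	-	+	-	+	+	-	-	+
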