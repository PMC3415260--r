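Der Morgenzug verließ den Bahnhof mit einigen Minuten Verspätung, und die
Reisenden sahen die Felder hinter den Fenstern vorbeiziehen, während sich
das Licht langsam veränderte. Man sagt oft, dass man eine Stadt am besten
kennenlernt, wenn man früh am Morgen durch ihre Straßen geht, wenn die
Läden noch geschlossen sind und nur die Bäcker schon arbeiten. Es gab eine
Zeit, in der jedes Dorf seinen eigenen Markt hatte, und die Leute kamen von
den umliegenden Höfen mit allem, was sie in der Woche angebaut oder
hergestellt hatten. Das Wetter kann in dieser Gegend sehr schnell
umschlagen, und Reisenden wird geraten, auch in den Sommermonaten einen
Mantel mitzunehmen. Sie schrieb jeden Sonntagabend Briefe an ihre
Freundinnen, erzählte von den kleinen Dingen der Woche und fragte nach
ihren Familien. Die Bibliothek an der Ecke ist seit mehr als hundert Jahren
geöffnet, und der Lesesaal riecht noch immer nach altem Papier und
poliertem Holz. Als die Brücke endlich fertig war, wuchsen die beiden
Hälften der Stadt zusammen, und eine Generation später konnte sich niemand
mehr erinnern, wie das Leben vorher gewesen war. Die meisten Menschen sind
sich einig, dass ein gutes Essen mit Freunden zu den einfachsten Freuden
des Alltags gehört.
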