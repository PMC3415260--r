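The morning train left the station a few minutes late, and the passengers
watched the fields slide past the windows while the light slowly changed.
It is often said that the best way to learn about a town is to walk its
streets early in the day, when the shops are still closed and the bakers
are the only people at work. There was a time when every village kept its
own market, and people would come from the surrounding farms with whatever
they had grown or made during the week. The weather in these parts can turn
quickly, so travellers are advised to carry a coat even in the summer
months. She wrote letters to her friends every Sunday evening, describing
the small things that had happened during the week and asking about their
families. The library on the corner has been open for more than a hundred
years, and the reading room still smells of old paper and polished wood.
When the bridge was finally finished, the two halves of the city grew
together, and within a generation nobody could remember how life had been
before. Most people agree that a good meal shared with friends is one of
the simplest and most reliable pleasures that daily life has to offer.
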